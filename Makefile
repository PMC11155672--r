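R ?= Rscript

install:
	R CMD INSTALL --no-docs --no-html --no-help .

test:
	$(R) -e 'testthat::test_dir("tests/testthat", package = "ReproScreen", load_package = "installed")'

reproduce:
	$(R) inst/scripts/reproscreen.R reproduce --out out/reproduce

acceptance:
	$(R) scripts/acceptance.R --seed 1 --out results/acceptance.json

.PHONY: install test reproduce acceptance
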