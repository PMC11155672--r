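# Brute-force two-sided Fisher p for a 2x2 table {{a, b}, {c, d}}:
# enumerate every table with the same margins, compute each table's
# hypergeometric probability from binomial coefficients, and sum the
# probabilities no larger than the observed one (same relative-error
# tie rule as the exact test convention).
fisher2x2Oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x), numeric(1))
  probs <- probs / sum(probs)
  sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)])
}

# Tiny five-chemical screen dataset with hand-chosen counts: two
# concentrations, two biological repeats, two technical replicates,
# 100 worms per well, no QC losses.
tinyWells <- function() {
  chems <- paste0("c", 1:5)
  grid <- expand.grid(tech_replicate = 1:2, bio_repeat = 1:2,
                      concentration = c(30, 100), chemical_id = chems,
                      stringsAsFactors = FALSE)
  # GFP+ counts: chemical effect grows with index; concentration 100
  # doubles it; replicate/repeat wiggle of 0 or 1
  base <- c(c1 = 0, c2 = 1, c3 = 2, c4 = 4, c5 = 8)
  grid$n_gfp_pos <- base[grid$chemical_id] *
    ifelse(grid$concentration == 100, 2L, 1L) +
    (grid$tech_replicate - 1L) + (grid$bio_repeat - 1L)
  grid$n_total <- 100L
  grid$n_dead <- 0L
  grid$ectopic <- FALSE
  grid$plate_id <- "P1"
  grid$well_position <- "A01"
  grid
}

# Spreadsheet-style recomputation of the tiny dataset's pipeline:
# plain loops, no shared code with the package internals.
tinyOracle <- function(wells, sigma = "sample") {
  chems <- sort(unique(wells$chemical_id))
  concs <- sort(unique(wells$concentration))
  x <- matrix(NA_real_, length(chems), length(concs),
              dimnames = list(chems, as.character(concs)))
  for (ch in chems) for (co in concs) {
    reps <- sort(unique(wells$bio_repeat[wells$chemical_id == ch &
                                           wells$concentration == co]))
    repMeans <- numeric(0)
    for (r in reps) {
      w <- wells[wells$chemical_id == ch & wells$concentration == co &
                   wells$bio_repeat == r, ]
      if (nrow(w)) repMeans <- c(repMeans,
                                 sum(w$n_gfp_pos / w$n_total) / nrow(w))
    }
    if (length(repMeans)) x[ch, as.character(co)] <-
        sum(repMeans) / length(repMeans)
  }
  z <- x
  for (j in seq_along(concs)) {
    v <- x[, j][!is.na(x[, j])]
    mu <- sum(v) / length(v)
    ss <- sum((v - mu)^2)
    s <- if (sigma == "population") sqrt(ss / length(v))
      else sqrt(ss / (length(v) - 1))
    z[, j] <- (x[, j] - mu) / s
  }
  list(x = x, z = z)
}
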