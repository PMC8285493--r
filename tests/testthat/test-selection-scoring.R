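# minimal counts matrix with reserved rows for n variants x samples
counts_fixture <- function(mat, wt = 1000L) {
  reserved <- matrix(0L, nrow = 5, ncol = ncol(mat),
                     dimnames = list(c("WT", "UNINTENDED", "MULTI",
                                       "UNALIGNABLE", "LOW_QUALITY"),
                                     colnames(mat)))
  reserved["WT", ] <- wt
  rbind(mat, reserved)
}

test_that("variant fractions follow the pseudocount formula over assigned reads", {
  m <- matrix(c(10L, 990L), ncol = 1, dimnames = list(c("v1", "v2"), "s"))
  f <- compute_fractions(counts_fixture(m, wt = 0L), pseudocount = 0)
  expect_equal(unname(f["v1", "s"]), 0.01)
  # doubling every count leaves fractions unchanged (pseudocount 0)
  f2 <- compute_fractions(counts_fixture(2L * m, wt = 0L), pseudocount = 0)
  expect_equal(f, f2)
  # pseudocount formula at zero count
  m3 <- matrix(c(0L, 1000L), ncol = 1, dimnames = list(c("v1", "v2"), "s"))
  f3 <- compute_fractions(counts_fixture(m3, wt = 0L), pseudocount = 0.5)
  expect_equal(unname(f3["v1", "s"]), 0.5 / 1000.5)
  # discard classes are not part of the denominator
  cf <- counts_fixture(m, wt = 0L)
  cf["MULTI", ] <- 5000L
  expect_equal(compute_fractions(cf, pseudocount = 0), f)
  expect_error(compute_fractions(counts_fixture(0L * m, wt = 0L)), "zero assigned")
})

test_that("the bottom-percentile filter follows the nearest-rank law", {
  set.seed(71)
  x100 <- runif(100)
  flags <- filter_low_t0(x100, 8)
  expect_equal(sum(flags), 8L)
  expect_true(all(x100[flags] <= min(x100[!flags])))
  expect_equal(sum(filter_low_t0(runif(50), 8)), 4L)  # ceiling(4) of 50
  expect_true(all(filter_low_t0(rep(0.3, 25), 8)))    # full tie: all flagged
})

test_that("survival LFC normalizes to T0 and compares arms", {
  sheet <- sample_sheet(c("t0a", "t0b", "da", "db", "ca", "cb"),
                        c("T0", "T0", "DNMDP100", "DNMDP100", "DMSO", "DMSO"),
                        c(1, 2, 1, 2, 1, 2))
  base <- c(v1 = 0.2, v2 = 0.3, v3 = 0.5)
  # treatment doubles v1, control unchanged
  fr <- cbind(t0a = base, t0b = base,
              da = c(0.4, 0.3, 0.5), db = c(0.4, 0.3, 0.5),
              ca = base, cb = base)
  lfc <- survival_lfc(fr, sheet, "DNMDP100", "DMSO")
  expect_equal(unname(lfc["v1"]), 1)
  # all conditions identical to T0: every LFC is zero, and no hits
  fr0 <- cbind(t0a = base, t0b = base, da = base, db = base,
               ca = base, cb = base)
  lfc0 <- survival_lfc(fr0, sheet, "DNMDP100", "DMSO")
  expect_equal(unname(lfc0), rep(0, 3))
  expect_false(any(call_hits(lfc0)))
  # replicate norms (2, 4) vs (1, 1): lfc = log2(3)
  fr2 <- cbind(t0a = base, t0b = base,
               da = base * 2, db = base * 4, ca = base, cb = base)
  lfc2 <- survival_lfc(fr2, sheet, "DNMDP100", "DMSO")
  expect_equal(unname(lfc2), rep(log2(3), 3))
  expect_error(survival_lfc(fr, sheet, "TREQ100", "DMSO"), "absent")
})

test_that("z-scores are standardized with the sample SD", {
  expect_equal(z_scores(c(-1, 0, 1)), c(-1, 0, 1))
  expect_error(z_scores(c(2, 2, 2)), "zero standard deviation")
  set.seed(73)
  for (i in 1:5) {
    z <- z_scores(rnorm(sample(10:500, 1), mean = 3, sd = 2))
    expect_lt(abs(mean(z)), 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("hit calling flags the positive tail beyond the SD threshold", {
  set.seed(79)
  lfc <- rnorm(10000)
  frac <- mean(call_hits(lfc))
  expect_equal(frac, 1 - pnorm(1), tolerance = 0.15)  # ~0.159, MC error
  expect_false(any(call_hits(rep(1.7, 20))))
  # monotonicity: raising one variant's treatment count never lowers its lfc
  sheet <- sample_sheet(c("t0", "d", "c"), c("T0", "DNMDP100", "DMSO"), c(1, 1, 1))
  set.seed(83)
  n <- 50
  counts0 <- matrix(rpois(n * 3, 100) + 1L, ncol = 3,
                    dimnames = list(paste0("v", 1:n), c("t0", "d", "c")))
  prev <- -Inf
  for (extra in c(0L, 10L, 100L, 1000L)) {
    cts <- counts0
    cts["v7", "d"] <- cts["v7", "d"] + extra
    lfc <- survival_lfc(compute_fractions(counts_fixture(cts)), sheet,
                        "DNMDP100", "DMSO")
    expect_gte(lfc[["v7"]], prev)
    prev <- lfc[["v7"]]
  }
})

test_that("scores are invariant to per-sample count rescaling", {
  orf <- synthetic_orf(40, seed = 91)
  d <- design_saturation_library(
    orf, design_constraints(1, 40, forbidden_sites = list()))
  fit <- fitness_model(d, example_resistance_set(d))
  sim <- simulate_screen(d, fit, screen_sim_config(depth = 2e5, dropout = 0,
                                                   seed = 91))
  params <- scoring_params(pseudocount = 0)
  s1 <- score_screen(sim$counts, sim$sheet, d, params)
  # guard: retained rows must be zero-free, else pseudocount-0 logs degenerate
  expect_true(all(sim$counts[s1$variant_id[!s1$low_confidence], ] > 0))
  scaled <- sim$counts
  scaled[, "DNMDP100_rep1"] <- 3L * scaled[, "DNMDP100_rep1"]
  scaled[, "T0_rep2"] <- 7L * scaled[, "T0_rep2"]
  s2 <- score_screen(scaled, sim$sheet, d, params)
  expect_equal(s2, s1)
})

test_that("screen scoring excludes low-confidence variants and annotates hits", {
  orf <- synthetic_orf(60, seed = 97)
  d <- design_saturation_library(
    orf, design_constraints(1, 60, forbidden_sites = list()))
  fit <- fitness_model(d, example_resistance_set(d))
  sim <- simulate_screen(d, fit, screen_sim_config(depth = 3e5, seed = 97))
  sc <- score_screen(sim$counts, sim$sheet, d)
  n <- nrow(sc)
  expect_equal(n, nrow(d$variants))
  expect_equal(sum(sc$low_confidence), ceiling(0.08 * n) +
                 sum(sc$t0_fraction == sort(sc$t0_fraction)[ceiling(0.08 * n)]) - 1L)
  expect_true(all(is.na(sc$lfc_dnmdp100_vs_dmso[sc$low_confidence])))
  expect_true(all(is.na(sc$z[sc$low_confidence])))
  keep <- !sc$low_confidence
  expect_lt(abs(mean(sc$z[keep])), 1e-10)
  expect_equal(sd(sc$z[keep]), 1, tolerance = 1e-10)
  # exclusion list suppresses hit flags without touching scores
  some_hit <- sc$variant_id[which(sc$resistance_hit)[1]]
  sc2 <- score_screen(sim$counts, sim$sheet, d, exclusion = some_hit)
  expect_false(sc2$resistance_hit[sc2$variant_id == some_hit])
  expect_equal(sc2$lfc_dnmdp100_vs_dmso, sc$lfc_dnmdp100_vs_dmso)
  # TREQ100 control column present and finite for retained variants
  expect_true(all(is.finite(sc$lfc_dnmdp100_vs_treq[keep])))
  # score table round trip
  path <- tempfile(fileext = ".tsv")
  write_score_table(sc, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), n)
})
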