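## brute-force reference implementations used as independent oracles
bf_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
bf_ccc <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y))) / length(x)
  sx <- sum((x - mean(x))^2) / length(x)
  sy <- sum((y - mean(y))^2) / length(y)
  2 * sxy / (sx + sy + (mean(x) - mean(y))^2)
}
bf_kendall <- function(x, y) {
  n <- length(x); conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}
bf_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
  }
  2 * inter / (na + nb)
}

test_that("AIC follows the Gaussian-SSE form and its monotonicity", {
  expect_equal(compute_aic(1, 100, 3), 100 * log(1 / 100) + 2 * 4)
  expect_lt(compute_aic(0.5, 100, 3), compute_aic(1, 100, 3))
  expect_lt(compute_aic(1, 100, 2), compute_aic(1, 100, 3))
  expect_gt(compute_aic(1, 100, 3, corrected = TRUE), compute_aic(1, 100, 3))
  expect_error(compute_aic(0, 100, 3), "epsilon")
  expect_error(compute_aic(1, 3, 3), "n_obs")
})

test_that("model ranking sorts by mean AIC with stable tie-breaking", {
  m <- matrix(c(10, 20, 5, 11, 30, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  rk <- rank_models(m, n_params = c(3, 2, 5))
  ## brute-force ordering of the means
  expect_equal(rk$model, names(sort(rowMeans(m))))
  ## single patient: ranking equals the per-patient ordering
  m1 <- matrix(c(3, 1, 2), dimnames = list(c("x", "y", "z"), NULL))
  expect_equal(rank_models(m1)$model, c("y", "z", "x"))
  ## shifting one patient's column leaves ranks unchanged
  m2 <- m; m2[, 2] <- m2[, 2] + 100
  expect_equal(rank_models(m2, n_params = c(3, 2, 5))$model, rk$model)
  ## ties break by parameter count
  mt <- matrix(c(1, 1), dimnames = list(c("big", "small"), NULL))
  expect_equal(rank_models(mt, n_params = c(4, 2))$model[1], "small")
  ## non-finite rows are excluded with a warning
  mb <- rbind(m, d = c(NaN, 1))
  expect_warning(rk2 <- rank_models(mb, n_params = c(3, 2, 5, 1)), "d")
  expect_equal(nrow(rk2), 3)
})

test_that("Dice endpoints, arithmetic, and symmetry hold", {
  a <- array(FALSE, c(4, 4, 1)); a[1:2, 1, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(4, 4, 1)); b[3:4, 4, 1] <- TRUE
  expect_equal(dice(a, b), 0)
  ab <- array(FALSE, c(4, 4, 1)); ab[c(2, 5)] <- TRUE  # |B|=2, overlap 1
  expect_equal(dice(a, ab), 0.5)
  expect_equal(dice(a, ab), dice(ab, a))
  empty <- array(FALSE, c(4, 4, 1))
  expect_warning(d <- dice(empty, empty), "vacuous")
  expect_equal(d, 1)
  expect_error(dice(a, array(FALSE, c(2, 2, 1))), "grids differ")
})

test_that("percent volume error is the signed relative error", {
  expect_equal(percent_volume_error(10, 10), 0)
  expect_equal(percent_volume_error(11, 10), 10)
  expect_equal(percent_volume_error(0, 10), -100)
  expect_error(percent_volume_error(1, 0), "> 0")
})

test_that("voxel agreement metrics match their closed forms", {
  m <- array(TRUE, c(3, 1, 1))
  x <- array(c(1, 2, 3), c(3, 1, 1)); y <- array(c(2, 3, 4), c(3, 1, 1))
  ag <- voxel_agreement(x, y, m)
  expect_equal(ag$pcc, 1)
  expect_equal(ag$ccc, 4 / 7)
  agi <- voxel_agreement(x, x, m)
  expect_equal(c(agi$pcc, agi$ccc), c(1, 1))
  agn <- voxel_agreement(x, -x, m)
  expect_equal(agn$pcc, -1)
  expect_lt(agn$ccc, 0)
  expect_error(voxel_agreement(x, array(1, c(3, 1, 1)), m), "zero variance")
})

test_that("Kendall correlation endpoints and the 2/3 case hold", {
  expect_equal(kcc(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(kcc(1:5, 5:1), -1)
  expect_equal(kcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  expect_error(kcc(c(1, 2), c(3, 3)), "tied")
})

test_that("metric implementations agree with brute force on random inputs", {
  set.seed(99)
  for (i in 1:250) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    ag <- voxel_agreement(array(x, c(n, 1, 1)), array(y, c(n, 1, 1)),
                          array(TRUE, c(n, 1, 1)))
    expect_equal(ag$pcc, bf_pearson(x, y), tolerance = 1e-12)
    expect_equal(ag$ccc, bf_ccc(x, y), tolerance = 1e-12)
    expect_lte(abs(ag$ccc), abs(ag$pcc) + 1e-12)
    xi <- sample(1:4, n, replace = TRUE)   # ties exercised
    yi <- sample(1:4, n, replace = TRUE)
    if (length(unique(xi)) > 1 && length(unique(yi)) > 1)
      expect_equal(kcc(xi, yi), bf_kendall(xi, yi), tolerance = 1e-12)
    a <- array(runif(24) > 0.5, c(4, 3, 2))
    b <- array(runif(24) > 0.5, c(4, 3, 2))
    if (any(a) || any(b))
      expect_equal(dice(a, b), bf_dice(as.logical(a), as.logical(b)),
                   tolerance = 1e-12)
  }
})

test_that("cell counts integrate fraction over voxel volume", {
  g <- image_grid(c(10, 1, 1), c(1, 1, 1))
  st <- tumor_state("single", 0, phi_T = array(0.5, g$shape))
  expect_equal(cell_count(st, g), 5)
  expect_equal(cell_count(tumor_state("single", 0,
                                      phi_T = array(0, g$shape)), g), 0)
  st2 <- st; st2$phi_T <- st$phi_T * 2 * 0.9
  expect_equal(cell_count(st2, g), 1.8 * cell_count(st, g))
  g2 <- image_grid(c(2, 2, 2), c(1, 2, 3))
  stt <- tumor_state("two_species", 0, phi_E = array(0.1, c(2, 2, 2)),
                     phi_N = array(0.2, c(2, 2, 2)))
  expect_equal(cell_count(stt, g2), 8 * 0.3 * 6)
})

test_that("evaluating a prediction against itself is perfect", {
  syn <- cached_synth("small")
  cfg <- small_phantom_config()
  meas_states <- lapply(syn$dataset$visits, function(v)
    assign_initial_state(v, "two_species", cfg$cellularity))
  rep <- evaluate_predictions(meas_states, syn$dataset,
                              params = cfg$cellularity, threshold = 0.05)
  m <- rep$metrics
  expect_true(all(m$value[m$metric == "dice"] == 1))
  expect_true(all(m$value[m$metric == "percent_volume_error"] == 0, na.rm = TRUE))
  expect_true(all(abs(m$value[m$metric %in% c("pcc", "ccc")] - 1) < 1e-12))
  expect_equal(rep$summary$kcc_volume, 1)
  expect_equal(rep$summary$kcc_cell_count, 1)
  ## row count: per visit, 3 regions x 2 global metrics + 2 local metrics
  expect_equal(nrow(m), length(syn$dataset$visits) * 8)
  ## a shifted mask scores the brute-force overlap
  st <- meas_states[[1]]
  shifted <- st
  shifted$phi_E <- gliomaRx:::shift3(st$phi_E, 1, 2L)
  shifted$phi_N <- gliomaRx:::shift3(st$phi_N, 1, 2L)
  rep2 <- evaluate_predictions(list(shifted), syn$dataset,
                               params = cfg$cellularity)
  d_pkg <- rep2$metrics$value[rep2$metrics$metric == "dice" &
                                rep2$metrics$region == "enhancing"]
  d_bf <- bf_dice(as.logical(shifted$phi_E >= 0.05),
                  as.logical(syn$dataset$visits[[1]]$enhancing_mask))
  expect_equal(d_pkg, d_bf)
})
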