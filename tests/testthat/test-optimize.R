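random_phis <- function(n, seed, scale = 1) {
  set.seed(seed)
  matrix(abs(rnorm(n * 80)) * scale, nrow = n)
}

test_that("gap statistics match their defining moments", {
  D <- random_phis(100, seed = 1)
  ## strong set identical to decoy set: zero mean difference
  st <- compute_gap_statistics(D, D)
  expect_equal(st$A, rep(0, 80), tolerance = 1e-12, ignore_attr = TRUE)

  ## identical decoys: zero covariance
  one <- D[rep(1, 5), ]
  st0 <- compute_gap_statistics(D[1, , drop = FALSE], one)
  expect_equal(max(abs(st0$B)), 0)

  ## population covariance equals the brute-force <phi phi^T> - <phi><phi^T>
  S <- random_phis(10, seed = 2)
  st <- compute_gap_statistics(S, D)
  ref_B <- crossprod(D) / nrow(D) - tcrossprod(colMeans(D))
  expect_equal(st$B, ref_B, tolerance = 1e-10)
  expect_equal(st$A, colMeans(D) - colMeans(S), tolerance = 1e-12)

  expect_error(compute_gap_statistics(S, D[1, , drop = FALSE]), "two decoys")
})

test_that("the optimizer inverts the covariance on its retained modes", {
  ## identity covariance: gamma is proportional to A
  set.seed(3)
  A <- rnorm(80)
  m <- solve_gamma(gap_statistics(A, diag(80)), n_modes = 80)
  expect_gt(abs(cosine(as.numeric(m$gamma), A)), 1 - 1e-12)
  expect_equal(sqrt(sum(m$gamma^2)), 1, tolerance = 1e-12)
  ## orientation: decoys above strong binders
  expect_gt(sum(A * as.numeric(m$gamma)), 0)

  ## full-rank random statistics: parallel to a dense linear solve
  for (seed in 1:5) {
    D <- random_phis(300, seed = seed)
    S <- random_phis(5, seed = seed + 100)
    st <- compute_gap_statistics(S, D)
    m <- solve_gamma(st, n_modes = 80)
    dense <- solve(st$B, st$A)
    expect_gt(abs(cosine(as.numeric(m$gamma), dense)), 0.999)
  }

  ## rank-deficient covariance refuses too many modes
  D_low <- random_phis(100, seed = 9)
  D_low[, 41:80] <- 0
  st_low <- compute_gap_statistics(random_phis(2, seed = 10), D_low)
  expect_error(solve_gamma(st_low, n_modes = 80), "insufficient decoy diversity")
  expect_s3_class(solve_gamma(st_low, n_modes = NULL), "energy_model")
})

test_that("predicted energy is the gamma-phi contraction", {
  m <- planted_energy_model(seed = 4)
  expect_equal(predict_energy(m, empty_phi_matrix <- matrix(0, 20, 4)), 0)
  set.seed(5)
  phi <- matrix(abs(rnorm(80)), 20, 4)
  e <- predict_energy(m, phi)
  expect_equal(e, sum(m$gamma * phi), tolerance = 1e-12)
  ## linearity in gamma
  m2 <- energy_model(3 * m$gamma)
  expect_equal(predict_energy(m2, phi), 3 * e, tolerance = 1e-12)
  ## stacked rows give a vector
  Phi <- random_phis(7, seed = 6)
  expect_equal(predict_energy(m, Phi), as.numeric(Phi %*% as.numeric(m$gamma)))
  expect_error(predict_energy(m, 1:10), "dimension")
})

test_that("Kd ratios convert to free energies with the gas constant", {
  expect_equal(ddg_from_kd(1), 0)
  expect_equal(ddg_from_kd(exp(1)), 1.98720425e-3 * 298.15, tolerance = 1e-12)
  expect_equal(ddg_from_kd(2.5), -ddg_from_kd(1 / 2.5), tolerance = 1e-12)
  expect_equal(kd_from_ddg(ddg_from_kd(0.37)), 0.37, tolerance = 1e-12)
  expect_error(ddg_from_kd(0), "positive")
  expect_error(ddg_from_kd(-1), "positive")
})

test_that("ridge calibration recovers a planted model and matches the closed form", {
  set.seed(7)
  Phi <- matrix(runif(200 * 80), nrow = 200)
  g_star <- rnorm(80)
  y <- as.numeric(Phi %*% g_star)

  ## noiseless, tiny regularization: near-exact recovery
  m <- fit_gamma_selex(Phi, y, alpha = 1e-10)
  rel_err <- sqrt(sum((as.numeric(m$gamma) - g_star)^2) / sum(g_star^2))
  expect_lt(rel_err, 1e-6)
  expect_equal(m$provenance, "selex-ridge")

  ## independent closed-form oracle at the working regularization
  y_noisy <- y + rnorm(200, sd = 0.3)
  m2 <- fit_gamma_selex(Phi, y_noisy, alpha = 0.01)
  oracle <- solve(crossprod(Phi) + 0.01 * diag(80), crossprod(Phi, y_noisy))
  expect_lt(max(abs(as.numeric(m2$gamma) - oracle)), 1e-10)

  ## shrinkage: the norm decreases monotonically in alpha
  norms <- vapply(c(0.01, 1, 100, 1e4), function(a)
    sqrt(sum(fit_gamma_selex(Phi, y_noisy, alpha = a)$gamma^2)), numeric(1))
  expect_true(all(diff(norms) < 0))

  expect_error(fit_gamma_selex(matrix(0, 10, 80), rnorm(10)), "all-zero")
})

test_that("gamma rescaling never changes predicted rankings", {
  sc <- small_scenario()
  m <- train_scenario(sc)
  Phi <- do.call(rbind, lapply(sc$decoys$dna[1:50], function(s)
    as.numeric(compute_phi(sc$complex, sc$interface, dna_seq = s))))
  e1 <- predict_energy(m, Phi)
  m_scaled <- energy_model(7.3 * m$gamma, provenance = m$provenance)
  e2 <- predict_energy(m_scaled, Phi)
  expect_equal(cor(e1, e2, method = "spearman"), 1)
})

test_that("the trained model beats random equal-norm models on the objective", {
  sc <- small_scenario()
  cg <- sc$complex; sel <- sc$interface
  pairs <- ideaEnergy:::interface_pairs(cg, sel)
  S <- rbind(
    ideaEnergy:::phi_matrix(cg, sel, dna_strings = sc$strong$dna, pairs = pairs),
    ideaEnergy:::phi_matrix(cg, sel, protein_strings = sc$strong$protein, pairs = pairs))
  D <- rbind(
    ideaEnergy:::phi_matrix(cg, sel, dna_strings = sc$decoys$dna, pairs = pairs),
    ideaEnergy:::phi_matrix(cg, sel, protein_strings = sc$decoys$protein, pairs = pairs))
  st <- compute_gap_statistics(S, D)
  m <- solve_gamma(st, n_modes = NULL)
  obj <- gap_ratio(m$gamma, st)
  set.seed(8)
  rand_obj <- replicate(200, {
    g <- rnorm(80); g <- g / sqrt(sum(g^2))
    gap_ratio(g, st)
  })
  expect_true(all(obj >= rand_obj))
})

test_that("recovery of a planted matrix improves with decoy count", {
  ## averaged over 20 seeds, cosine to the planted matrix increases
  ## monotonically across decoy counts 50 -> 200 -> 1000
  mean_cos <- vapply(c(50, 200, 1000), function(nd) {
    mean(vapply(1:20, function(s) {
      sc <- make_training_scenario(n_protein = 12, n_dna = 8, n_contacts = 16,
                                   seed = 6000 + s, n_dna_decoys = nd,
                                   n_protein_decoys = 2 * nd)
      m <- train_scenario(sc)
      cosine(as.numeric(m$gamma), as.numeric(sc$gamma_star$gamma))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cos) > 0))
})

test_that("energy model TSV round trip is lossless", {
  m <- train_scenario(small_scenario())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gamma_tsv(m, f)
  back <- read_gamma_tsv(f)
  expect_equal(back$gamma, m$gamma, tolerance = 1e-12)
  expect_equal(back$provenance, m$provenance)
  expect_equal(back$n_modes, m$n_modes)
})
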