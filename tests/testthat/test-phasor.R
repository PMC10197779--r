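test_that("temporal phasors match the mono-exponential closed form", {
  ta <- seq(0.025, 60, by = 0.05)   # long window so truncation is negligible
  for (tau in c(0.5, 1.5, 4)) {
    gs <- phasor_transform(synthesize_decay(tau, 1e4, ta), ta, "temporal")
    omega <- attr(gs, "omega")
    want <- phasor_monoexp(tau, omega)
    expect_equal(unname(gs[c("G", "S")]), unname(want), tolerance = 1e-3)
    # on the universal semicircle
    expect_equal((gs[["G"]] - 0.5)^2 + gs[["S"]]^2, 0.25, tolerance = 1e-3)
  }
  # delta decay (tau -> 0) sits at (1, 0)
  delta <- c(1, numeric(length(ta) - 1))
  gs0 <- phasor_transform(delta, ta, "temporal")
  expect_equal(unname(gs0["G"]), 1, tolerance = 1e-2)
  expect_equal(unname(gs0["S"]), 0, tolerance = 1e-2)
})

test_that("mixtures land on intensity-weighted phasor combinations", {
  ta <- seq(0.025, 60, by = 0.05)
  a <- synthesize_decay(1, 5e3, ta)
  b <- synthesize_decay(4, 5e3, ta)
  gab <- phasor_transform(a + b, ta, "temporal")
  ga <- phasor_transform(a, ta, "temporal")
  gb <- phasor_transform(b, ta, "temporal")
  expect_equal(unname(gab[c("G", "S")]),
               unname((ga[c("G", "S")] + gb[c("G", "S")]) / 2),
               tolerance = 1e-3)
  # multi-exponential mixtures lie strictly inside the semicircle
  expect_lt((gab[["G"]] - 0.5)^2 + gab[["S"]]^2, 0.25 - 1e-4)
})

test_that("spectral phasors place a mid-range Gaussian at phase pi", {
  wl <- seq(500, 700, by = 0.5)
  spec <- exp(-(wl - 600)^2 / (2 * 15^2))
  gs <- phasor_transform(spec, wl, "spectral")
  phase <- atan2(gs[["S"]], gs[["G"]]) %% (2 * pi)
  # numeric-integration oracle with the same phase convention
  phi <- 2 * pi * (wl - min(wl)) / diff(range(wl))
  oracle <- atan2(sum(spec * sin(phi)) / sum(spec),
                  sum(spec * cos(phi)) / sum(spec)) %% (2 * pi)
  expect_equal(phase, oracle, tolerance = 1e-12)
  expect_equal(phase, pi, tolerance = 0.05)
})

test_that("degenerate signals flag an undefined phasor", {
  gs <- phasor_transform(numeric(10), 1:10, "temporal")
  expect_true(is.na(gs[["G"]]))
  expect_true(attr(gs, "undefined"))
})

test_that("cluster probabilities separate distinct phasor blobs", {
  set.seed(5)
  blob1 <- cbind(rnorm(150, 0.3, 0.005), rnorm(150, 0.45, 0.005))
  blob2 <- cbind(rnorm(150, 0.8, 0.005), rnorm(150, 0.35, 0.005))
  cloud <- tibble::tibble(G = c(blob1[, 1], blob2[, 1]),
                          S = c(blob1[, 2], blob2[, 2]))
  truth <- rep(1:2, each = 150)
  cl <- cluster_probabilities(cloud, 2, seed = 4)
  p <- as.matrix(cl[, c("p1", "p2")])
  # rows are normalized probabilities
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  # every point confidently assigned to its own blob (labels by phase order)
  own <- ifelse(cl$cluster == truth, p[cbind(1:300, truth)], NA)
  agreement <- mean(cl$cluster == truth)
  flipped <- mean(cl$cluster == 3 - truth)
  expect_true(max(agreement, flipped) == 1)
  expect_true(all(pmax(p[, 1], p[, 2]) > 0.99))
  # determinism under a fixed seed
  cl2 <- cluster_probabilities(cloud, 2, seed = 4)
  expect_equal(cl$p1, cl2$p1, tolerance = 0)

  one <- cluster_probabilities(cloud, 1)
  expect_true(all(one$p1 == 1))
  degenerate <- tibble::tibble(G = rep(0.5, 10), S = rep(0.2, 10))
  expect_error(cluster_probabilities(degenerate, 2), "clustering error")
})

test_that("amplitude-fraction unmixing inverts the probability model", {
  f <- tibble::tibble(f1 = 0.1, f2 = 0.2, f3 = 0.3, f4 = 0.4)
  p <- fractions_to_probabilities(f)
  expect_equal(unname(unlist(p)), c(0.3, 0.7, 0.1, 0.5, 0.4))
  back <- unmix_fractions(p)
  expect_equal(unlist(back[, 1:4]), unlist(f), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$residual, 0)

  pure <- fractions_to_probabilities(
    tibble::tibble(f1 = 1, f2 = 0, f3 = 0, f4 = 0))
  expect_equal(unname(unlist(pure)), c(0, 1, 1, 0, 0))
  expect_equal(unlist(unmix_fractions(pure)[, 1:4]), c(1, 0, 0, 0),
               ignore_attr = TRUE)

  # property: inversion is the identity across the simplex
  set.seed(11)
  draws <- matrix(rexp(4 * 50), ncol = 4)
  draws <- draws / rowSums(draws)
  fr <- tibble::as_tibble(as.data.frame(draws))
  names(fr) <- paste0("f", 1:4)
  rt <- unmix_fractions(fractions_to_probabilities(fr))
  expect_equal(as.matrix(rt[, 1:4]), as.matrix(fr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(rt$residual < 1e-12))

  bad <- tibble::tibble(paL = 0.3, pbL = 0.7, paT = 0.1, pbT = 0.3,
                        pcT = 0.4)
  expect_error(unmix_fractions(bad), "input error")
})

test_that("phasor clouds from image cubes mask dim pixels", {
  ta <- (seq_len(80) - 0.5) * 0.05
  cube <- array(0, c(5, 5, 80))
  cube[2, 2, ] <- synthesize_decay(2, 1e4, ta)
  cube[4, 4, ] <- synthesize_decay(0.5, 1e4, ta)
  cloud <- phasor_cloud(cube, ta, "temporal")
  expect_equal(nrow(cloud), 2)
  expect_true(all(c("G", "S", "intensity") %in% names(cloud)))
  # the shorter lifetime has the larger G
  expect_gt(cloud$G[cloud$row == 4], cloud$G[cloud$row == 2])
})
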