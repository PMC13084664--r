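test_that("the fixed-point solution reproduces worked per-AA demands", {
  thr <- solve_mmd(c(
    pto_pp = 2.6, pto_pa = 6.5, egl = 14.5, ufaap = 0.9, hsnm = 1.5, ol = 0
  ))
  expect_equal(round(thr$mmd$mean, 1), 36.6)
  expect_equal(round(thr$io$mean, 1), 10.6)

  ile <- solve_mmd(c(2.2, 5.4, 6.4, 0.3, 0.9, 0))
  expect_equal(round(ile$mmd$mean, 1), 21.4)
  expect_equal(round(ile$io$mean, 1), 6.2)

  gly <- solve_mmd(c(6.9, 17.2, 11.7, 12.0, 3.2, 17.2))
  expect_equal(round(gly$mmd$mean, 1), 96.1)

  zero <- solve_mmd(rep(0, 6))
  expect_identical(zero$mmd$mean, 0)
  expect_identical(zero$io$mean, 0)
})

test_that("solver validates inputs and the oxidation rate", {
  expect_error(model_constants(io_rate = 1), "infeasible")
  expect_error(model_constants(io_rate = 1.2), "infeasible")
  expect_error(solve_mmd(c(-1, 0, 0, 0, 0, 0)), "non-negative")
  expect_error(solve_mmd(c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6)), "missing component")
  expect_error(solve_mmd(c(1, 2, 3)), "6 non-IO")
})

test_that("closed form agrees with the iterative fixed-point oracle", {
  # oracle: MMD_{t+1} = S + r * MMD_t from 0 is a geometric series in r
  iterate_mmd <- function(s, r, iters = 200L) {
    m <- 0
    for (i in seq_len(iters)) m <- s + r * m
    m
  }
  per <- default_fit()$per_aa
  comps <- paste0(c("pto_pp", "pto_pa", "egl", "ufaap", "hsnm", "ol"), "_mean")
  for (i in seq_len(nrow(per))) {
    s <- sum(unlist(per[i, comps]))
    expect_equal(per$mmd_mean[i], iterate_mmd(s, 0.29), tolerance = 1e-9)
  }
  # fixed-point identity: non-IO sum + IO = MMD exactly
  expect_equal(
    rowSums(per[, comps]) + per$io_mean, per$mmd_mean,
    ignore_attr = TRUE
  )
})

test_that("the solver is homogeneous of degree 1 in the components", {
  set.seed(7)
  for (rep in 1:20) {
    x <- stats::runif(6, 0, 20)
    k <- stats::runif(1, 0, 5)
    base <- solve_mmd(x)
    scaled <- solve_mmd(k * x)
    expect_equal(scaled$mmd$mean, k * base$mmd$mean)
    expect_equal(scaled$io$mean, k * base$io$mean)
  }
})

test_that("root-sum-of-squares propagation behaves as stated", {
  expect_equal(propagate_sd(c(3, 4)), 5)
  for (x in c(0, 0.3, 7)) expect_equal(propagate_sd(x), x)
  expect_error(propagate_sd(c(1, -1)), "non-negative")

  set.seed(11)
  for (rep in 1:20) {
    v <- stats::runif(5, 0, 3)
    # permutation invariance
    expect_equal(propagate_sd(sample(v)), propagate_sd(v))
    # monotone non-decreasing in each argument
    i <- sample(5, 1)
    v2 <- v
    v2[i] <- v2[i] + stats::runif(1, 0, 2)
    expect_gte(propagate_sd(v2), propagate_sd(v))
  }
})

test_that("MMD uncertainty combines the seven loss terms", {
  # with a directly estimated IO SD the terms combine by plain RSS
  thr <- solve_mmd(
    c(pto_pp = 2.6, pto_pa = 6.5, egl = 14.5, ufaap = 0.9, hsnm = 1.5, ol = 0),
    sds = c(
      pto_pp = 2.2, pto_pa = 1.2, egl = 1.9, ufaap = 0.1, hsnm = 0.3, ol = 0
    ),
    io_sd = 0.7
  )
  expect_equal(round(thr$mmd$sd, 2), 3.24)
  expect_equal(thr$io$sd, 0.7)

  # fallback: IO SD scaled from the non-IO RSS when no override is given
  sds <- c(pto_pp = 1, pto_pa = 2, egl = 2, ufaap = 0.5, hsnm = 0.5, ol = 0)
  sol <- solve_mmd(rep(1, 6), sds = sds)
  rss <- sqrt(sum(sds^2))
  expect_equal(sol$io$sd, 0.29 * rss / 0.71)
  expect_equal(sol$mmd$sd, sqrt((0.29 * rss / 0.71)^2 + rss^2))
})

test_that("aggregation to class totals matches the published sums", {
  printed <- c(
    His = 22.5, Ile = 21.4, Leu = 39.7, Lys = 36.8, SAA = 26.3, AAA = 41.6,
    Thr = 36.6, Trp = 7.5, Val = 29.8, Ala = 34.5, Arg = 36.3, Asx = 55.0,
    Glx = 75.8, Gly = 96.0, Pro = 42.8, Ser = 31.4
  )
  keys <- aa_keys()
  per <- data.frame(
    aa = names(printed), class = keys$class[match(names(printed), keys$aa)],
    mmd_mean = unname(printed)
  )
  tot <- aggregate_mmd(per)
  expect_equal(tot$mean[tot$group == "total_iaa"], 262.2)
  expect_equal(tot$mean[tot$group == "total_daa"], 371.8)
  expect_equal(
    tot$mean[tot$group == "total_protein"],
    tot$mean[tot$group == "total_iaa"] + tot$mean[tot$group == "total_daa"]
  )

  per$mmd_mean <- 0
  tot0 <- aggregate_mmd(per)
  expect_true(all(tot0$mean == 0))

  expect_error(aggregate_mmd(per[-1, ]), "missing amino acid")
})

test_that("loss-source proportions split the demand as published", {
  fit <- default_fit()
  pr <- source_proportions(fit)
  # per AA the seven individual source shares sum to 1
  seven <- pr[pr$source != "tol", ]
  sums <- tapply(seven$share, seven$aa, sum)
  expect_equal(as.vector(sums), rep(1, 16), tolerance = 1e-12)
  # EGL dominates the threonine demand at ~40%
  expect_equal(
    pr$share[pr$aa == "Thr" & pr$source == "egl"], 0.396,
    tolerance = 0.002
  )
  # total oxidative losses contribute ~72% of the lysine demand
  expect_equal(
    pr$share[pr$aa == "Lys" & pr$source == "tol"], 0.720,
    tolerance = 0.002
  )
  # degenerate cases
  single <- zero_loss_table()
  single$egl_mean <- 5
  fit1 <- solve_mmd_table(single)
  pr1 <- source_proportions(fit1, aa = "His")
  expect_equal(pr1$share[pr1$source == "egl"], 0.71)
  expect_equal(pr1$share[pr1$source == "io"], 0.29)
  expect_error(
    source_proportions(solve_mmd_table(zero_loss_table())),
    "zero MMD"
  )
})

test_that("IAA share of the protein demand matches both requirement bases", {
  expect_lt(abs(iaa_share(default_fit()) - 41.4), 0.15)
  fao <- data.frame(
    group = c("total_iaa", "total_daa", "total_protein"),
    mean = c(184, 476, 660)
  )
  expect_equal(iaa_share(fao), 27.9, tolerance = 0.002)
  eq <- data.frame(group = c("total_iaa", "total_protein"), mean = c(5, 10))
  expect_equal(iaa_share(eq), 50)
  expect_error(
    iaa_share(data.frame(group = "total_protein", mean = 1)),
    "total_iaa"
  )
})
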