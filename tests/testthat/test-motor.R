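test_that("motor schedule obeys the block recipe for every seed", {
  for (seed in c(1, 17, 99)) {
    sch <- motor_schedule(seed = seed, participant = seed %% 3)
    tr <- sch[sch$session == "training", ]
    te <- sch[sch$session == "testing", ]

    # 24 training blocks, each with two triplets whose exposures are
    # {B+, R-} in some order
    expect_equal(sort(unique(tr$block)), 1:24)
    for (b in 1:24) {
      blk <- tr[tr$block == b, ]
      expos <- blk[blk$role == "triplet_exposure", ]
      expect_equal(nrow(expos), 2)
      expect_setequal(paste0(expos$background, expos$perturbation),
                      c("B+", "R-"))
      # 32-trial perturbation section balanced within each consecutive 8
      pert <- blk[blk$role == "standard", ]
      expect_equal(nrow(pert), 32)
      for (g in 0:3) {
        eight <- pert[g * 8 + 1:8, ]
        expect_equal(sum(eight$background == "B" & eight$perturbation == "+"), 4)
        expect_equal(sum(eight$background == "R" & eight$perturbation == "-"), 4)
      }
      # washout trials balanced between B0 and R0
      wash <- blk[blk$role == "washout", ]
      expect_equal(sum(wash$background == "B"), sum(wash$background == "R"))
      expect_true(all(wash$perturbation == "0"))
    }

    # training washout lengths come from the stated replenished pools
    wash1 <- vapply(1:24, function(b) {
      blk <- tr[tr$block == b, ]
      first_trip <- min(which(blk$role == "triplet_pre"))
      sum(blk$role[seq_len(first_trip - 1)] == "washout")
    }, numeric(1))
    expect_true(all(wash1 %in% c(14, 16, 18)))
    # sampling without replacement: each value appears once per 3 blocks
    for (g in split(wash1, rep(1:8, each = 3))) {
      expect_setequal(g, c(14, 16, 18))
    }

    # testing: 8 repetitions x 4 combinations = 32 triplets
    expos <- te[te$role == "triplet_exposure", ]
    expect_equal(nrow(expos), 32)
    expect_equal(as.vector(table(expos$combination)), rep(8L, 4))
    # triplets are B0 / exposure / B0
    pre <- te[te$role == "triplet_pre", ]
    post <- te[te$role == "triplet_post", ]
    expect_true(all(pre$background == "B" & pre$perturbation == "0"))
    expect_true(all(post$background == "B" & post$perturbation == "0"))
    # testing washouts drawn from {2, 4, 6}
    for (b in unique(te$block)) {
      nw <- sum(te$block == b & te$role == "washout")
      expect_true(nw %in% c(2, 4, 6))
    }
  }
})

test_that("counterbalancing alternates across consecutive blocks", {
  sch <- motor_schedule(seed = 4, participant = 1)
  tr <- sch[sch$session == "training", ]
  first_expo <- vapply(1:24, function(b) {
    blk <- tr[tr$block == b, ]
    e <- blk[blk$role == "triplet_exposure", ]
    paste0(e$background[1], e$perturbation[1])
  }, character(1))
  expect_true(all(first_expo[seq(1, 23, 2)] != first_expo[seq(2, 24, 2)]))
})

test_that("the one-to-one input wiring survives training", {
  net <- motor_network(seed = 2, init_sd = 0.1)
  for (i in 1:20) {
    net <- learn_step(net, if (i %% 2) "pc" else "bp",
                      c(1, 0), c(1, 0), alpha = 0.1)
  }
  expect_equal(net$weights[[1]][1, 2], 0)
  expect_equal(net$weights[[1]][2, 1], 0)
})

test_that("zero learning rates yield zero adaptation change", {
  res <- run_motor_experiment("pc", init_sd = 0.05, lr_input = 0,
                              lr_output = 0, n_participants = 1, seed = 3)
  expect_equal(unname(res$mean_change), rep(0, 4))
})

test_that("analytic scale fit matches its closed form and a grid oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(fit_scale(x, x)$a, 1)
  expect_equal(fit_scale(x, x)$objective, 0)
  f <- fit_scale(x, x, with_bias = TRUE)
  expect_equal(f$a, 1)
  expect_equal(f$b, 0)

  # positivity clip
  expect_equal(fit_scale(c(1, 1, 1, 1), c(-1, -1, -1, -1))$a, 0)
  fb <- fit_scale(c(1, 2, 3, 4), c(4, 3, 2, 1), with_bias = TRUE)
  expect_equal(fb$a, 0)
  expect_equal(fb$b, 2.5)

  # dense 1-D grid minimization oracle
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(4)
    d <- rnorm(4)
    a_grid <- seq(0, 5, by = 1e-4)
    obj <- vapply(a_grid, function(a) sum((a * x - d)^2), numeric(1))
    expect_equal(fit_scale(x, d)$a, a_grid[which.min(obj)], tolerance = 1e-3)
  }
  expect_error(fit_scale(c(0, 0), c(1, 2)), "degenerate")
})

test_that("grid search returns the argmin of the residual objective", {
  d <- c("B+" = 1, "R+" = 0.5, "B-" = 0.4, "R-" = 0.1)
  g <- grid_search_fit("bp", "motor", d,
                       grids = list(init_sd = c(0.01, 0.1),
                                    lr_input = 0.01, lr_output = c(0.01, 0.05)),
                       n_participants = 1, seed = 5)
  expect_equal(nrow(g$results), 4)
  expect_equal(min(g$results$objective), g$best$fit$objective)
  expect_gte(g$best$fit$a, 0)

  single <- grid_search_fit("bp", "motor", d,
                            grids = list(init_sd = 0.05, lr_input = 0.01,
                                         lr_output = 0.01),
                            n_participants = 1, seed = 5)
  expect_equal(single$best$params$init_sd, 0.05)
  expect_equal(nrow(single$results), 1)
})
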