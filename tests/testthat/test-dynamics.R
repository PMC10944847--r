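test_that("discrepancy is the sum of absolute deviations from sources", {
  st <- make_state(c(0, 1, -1, 2), matrix(c(2L, 1L, 1L, 1L,
                                            3L, 3L, 2L, 2L,
                                            4L, 4L, 4L, 3L), ncol = 3))
  expect_equal(discrepancy(st, 1), 1 + 1 + 2)
  st2 <- make_state(c(0.5, 0.5, 0.5), matrix(c(2L, 1L, 1L, 3L, 3L, 2L), ncol = 2))
  expect_equal(discrepancy(st2, 1), 0)
  expect_error(discrepancy(st, 9), "invalid")
  # binary: True agent with sources {T,T,F,F,F} disagrees three times
  cond <- make_model_spec("condorcet", n = 7)
  stc <- make_state(c(1, 1, 1, 0, 0, 0, 1),
                    matrix(rep(2:6, 7), ncol = 5, byrow = TRUE), 0, spec = cond)
  expect_equal(discrepancy(stc, 1), 3)
})

test_that("naive learning adopts the source median and minimizes discrepancy", {
  src <- matrix(rep(2:6, 6), ncol = 5, byrow = TRUE)
  st <- make_state(c(0, 0.1, 0.5, 0.9, 0.2, 0.3), src)
  st2 <- naive_learning_action(st, 1)
  expect_equal(st2$opinions[1], 0.3)
  # binary majority: 3 of 5 True
  cond <- make_model_spec("condorcet", n = 7)
  stc <- make_state(c(0, 1, 1, 1, 0, 0, 1),
                    matrix(rep(2:6, 7), ncol = 5, byrow = TRUE), 0, spec = cond)
  expect_equal(naive_learning_action(stc, 1)$opinions[1], 1)
  # fixed point: opinion already the median
  st3 <- naive_learning_action(st2, 1)
  expect_identical(st3$opinions, st2$opinions)
})

test_that("the adopted median minimizes the sum of absolute deviations", {
  set.seed(13)
  for (rep in 1:50) {
    st <- random_state(n = 10, k = sample(2:5, 1))
    i <- sample(10, 1)
    after <- naive_learning_action(st, i)
    d_star <- discrepancy(after, i)
    for (cand in c(st$opinions, stats::runif(20, -4, 4))) {
      st_c <- st
      st_c$opinions[i] <- cand
      expect_gte(discrepancy(st_c, i) + 1e-12, d_star)
    }
  }
})

test_that("selective exposure rewires to the enumerated candidate", {
  # agent 1 at 0; sources at 0.1, 0.2, 5.0; non-sources at 0.05, 7.0
  x <- c(0, 0.1, 0.2, 5.0, 0.05, 7.0)
  src <- matrix(rep(c(2L, 3L, 4L), 6), ncol = 3, byrow = TRUE)
  st <- make_state(x, src, beta = 1)
  st2 <- selective_exposure_action(st, 1)
  expect_setequal(st2$graph$sources[1, ], c(2L, 3L, 5L)) # drops 4, adds 5
  expect_identical(st2$opinions, st$opinions)            # opinions never change
})

test_that("selective exposure no-ops on zero discrepancy or empty candidate set", {
  # all sources agree exactly
  st <- make_state(rep(1, 5), matrix(rep(c(2L, 3L), 5), ncol = 2, byrow = TRUE))
  expect_identical(selective_exposure_action(st, 1)$graph$sources,
                   st$graph$sources)
  # every non-source farther than the worst source
  x <- c(0, 0.1, 0.2, 9, 9.5)
  src <- matrix(rep(c(2L, 3L), 5), ncol = 2, byrow = TRUE)
  src[1, ] <- c(2L, 3L)
  st2 <- make_state(x, src)
  out <- selective_exposure_action(st2, 1)
  expect_identical(out$graph$sources, st2$graph$sources)
  expect_equal(ncol(out$graph$sources), 2) # in-degree conserved
})

test_that("selective exposure strictly reduces discrepancy when it acts", {
  set.seed(23)
  acted <- 0
  for (rep in 1:200) {
    st <- random_state(n = 12, k = 3, beta = 1)
    i <- sample(12, 1)
    before <- discrepancy(st, i)
    st2 <- selective_exposure_action(st, i)
    if (!identical(st2$graph$sources, st$graph$sources)) {
      acted <- acted + 1
      expect_lt(discrepancy(st2, i), before)
    }
  }
  expect_gt(acted, 50) # the property was actually exercised
})

test_that("round updates conserve structure and respect the beta limits", {
  set.seed(31)
  for (model in c("condorcet", "galton")) {
    spec <- make_model_spec(model, n = if (model == "condorcet") 21 else 20)
    # beta = 1: opinions immutable element-wise
    st <- random_state(n = spec$n, k = 4, beta = 1, spec = spec)
    out <- step_round(st)
    expect_identical(out$state$opinions, st$opinions)
    # beta = 0: edges immutable
    st0 <- random_state(n = spec$n, k = 4, beta = 0, spec = spec)
    out0 <- step_round(st0)
    expect_identical(out0$state$graph$sources, st0$graph$sources)
    # in-degree k and m = nk conserved at intermediate beta
    sth <- random_state(n = spec$n, k = 4, beta = 0.5, spec = spec)
    outh <- step_round(sth)$state
    expect_identical(dim(outh$graph$sources), dim(sth$graph$sources))
    expect_silent(selexpo:::validate_source_graph(outh$graph))
    expect_equal(outh$round, sth$round + 1L)
  }
})

test_that("is_steady detects fixed points and non-fixed points", {
  # consensus is steady for every beta
  st <- make_state(rep(0.4, 6), matrix(rep(c(2L, 3L), 6), ncol = 2, byrow = TRUE))
  for (b in c(0, 0.5, 1)) {
    st$beta <- b
    expect_true(is_steady(st))
  }
  # beta = 1 with a strictly nearer non-source is not steady
  x <- c(0, 0.1, 5, 0.05, 1)
  src <- matrix(rep(c(2L, 3L), 5), ncol = 2, byrow = TRUE)
  st2 <- make_state(x, src, beta = 1)
  expect_false(is_steady(st2))
  # beta = 0 ignores the graph side entirely
  st3 <- make_state(c(0.1, 0.1, 0.1, 9), matrix(c(2L, 1L, 1L, 1L,
                                                  3L, 3L, 2L, 2L), ncol = 2),
                    beta = 0)
  expect_false(is_steady(st3))          # agent 4 is off its source median
  st3$opinions[4] <- 0.1
  expect_true(is_steady(st3))
})

test_that("converged runs end in states that are steady and idempotent", {
  for (model in c("condorcet", "galton", "bimodal", "exponential")) {
    spec <- make_model_spec(model)
    for (beta in c(0, 0.3, 1)) {
      res <- run_simulation(spec, beta = beta, seed = 1000 + beta * 10)
      expect_true(res$converged)
      expect_true(is_steady(res$state))
      # stepping a steady state changes nothing
      expect_false(step_round(res$state)$changed)
    }
  }
})

test_that("runs are bit-identical under the same seed", {
  spec <- make_model_spec("bimodal")
  a <- run_simulation(spec, beta = 0.4, seed = 77)
  b <- run_simulation(spec, beta = 0.4, seed = 77)
  expect_identical(a, b)
  r1 <- run_simulation(spec, beta = 0.4, seed = 77, engine = "r",
                       max_rounds = 300)
  r2 <- run_simulation(spec, beta = 0.4, seed = 77, engine = "r",
                       max_rounds = 300)
  expect_identical(r1, r2)
})

test_that("beta = 1 preserves the opinion multiset and the initial aggregate", {
  for (model in c("condorcet", "exponential")) {
    spec <- make_model_spec(model)
    res <- run_simulation(spec, beta = 1, seed = 5)
    expect_identical(res$state$opinions, res$initial_opinions)
    expect_equal(aggregate_opinions(res$state$opinions, spec$aggregation_rule),
                 aggregate_opinions(res$initial_opinions, spec$aggregation_rule))
  }
})

test_that("beta = 0 keeps the graph and shrinks opinion diversity", {
  spec <- make_model_spec("galton")
  res <- run_simulation(spec, beta = 0, seed = 6, record_trajectory = TRUE)
  expect_identical(res$state$graph$sources, res$initial_sources)
  div <- res$trajectory$opinion_diversity
  expect_true(all(diff(div) <= 1e-12))  # sigma_x non-increasing over rounds
  expect_lt(div[length(div)], div[1])
})

test_that("the R reference engine agrees with the compiled engine's fixed points", {
  spec <- make_model_spec("galton", n = 20)
  for (beta in c(0, 0.5, 1)) {
    res_r <- run_simulation(spec, k = 3, beta = beta, seed = 91, engine = "r",
                            max_rounds = 500)
    expect_true(res_r$converged)
    expect_true(is_steady(res_r$state))
    res_c <- run_simulation(spec, k = 3, beta = beta, seed = 91)
    # same seed, same initial conditions; both must settle on steady states
    expect_identical(res_c$initial_opinions, res_r$initial_opinions)
    expect_identical(res_c$initial_sources, res_r$initial_sources)
    expect_true(is_steady(res_c$state))
  }
})

test_that("hitting the round cap is reported, not hidden", {
  spec <- make_model_spec("galton", n = 30)
  expect_warning(res <- run_simulation(spec, beta = 0.5, seed = 8,
                                       max_rounds = 1L), "cap")
  expect_false(res$converged)
  expect_equal(res$rounds_to_steady, 1L)
})
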