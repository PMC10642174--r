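test_that("hidden nodes decoupled from the observation impose no penalty", {
  # hidden m1 feeds nothing observed; observed pair is freely consistent
  nodes <- data.frame(id = c("m1", "m2", "b1"),
                      kind = c("molecular", "molecular", "behavioral"),
                      polarity = c("none", "none", "severity"))
  net <- logic_network(data.frame(source = c("m1", "m2"),
                                  target = c("m2", "m1"), sign = 1), nodes)
  prog <- logic_program(net, tau = 3L, weight = 1L)
  sub <- subject_profile("s", c(b1 = 2L), net)
  imp <- impute_hidden(net, prog, sub, "has_predecessor",
                       want_presence = TRUE)
  expect_true(imp$feasible)
  expect_equal(imp$departure$absolute, 0L)  # b1 has no regulators: it holds
  # every hidden level remains attainable among the optima
  expect_true(all(imp$levels_attained[, c("m1", "m2")]))
})

test_that("imputation under the planted program recovers the planted state", {
  for (seed in 1:10) {
    b <- generate_study("small", seed = seed)
    hid <- b$network$nodes$id[b$network$nodes$kind != "behavioral"]
    expect_lte(length(hid), 7)
    for (s in seq_along(b$observed)) {
      imp <- impute_hidden(b$network, b$truth_program, b$observed[[s]],
                           "has_predecessor", want_presence = TRUE)
      expect_true(imp$feasible)
      expect_equal(imp$departure$absolute, 0L)
      # the planted full state is among the departure-optimal completions
      truth <- b$truth_states[s, ]
      expect_true(all(vapply(hid, function(h) {
        imp$levels_attained[as.character(truth[[h]]), h]
      }, TRUE)))
    }
  }
})

test_that("imputation agrees with brute-force enumeration over completions", {
  for (seed in 1:25) {
    inst <- toy_instance(seed)
    prog <- sample_program(inst$net)
    ed <- o_edge_table(inst$net, prog)
    for (mode in c("pred", "fixed")) {
      ref <- o_impute(inst$net$nodes$id, inst$subjects[[1]]$observed, ed,
                      mode)
      imp <- impute_hidden(inst$net, prog, inst$subjects[[1]],
                           if (mode == "pred") "has_predecessor"
                           else "fixed_point",
                           config = fit_config(optima_cap = 5000L))
      if (is.na(ref$dev)) {
        expect_false(imp$feasible)
      } else {
        expect_true(imp$feasible)
        expect_equal(imp$departure$absolute, as.integer(ref$dev))
        expect_setequal(apply(imp$states, 1, paste, collapse = ","),
                        apply(ref$states, 1, paste, collapse = ","))
      }
    }
  }
})

test_that("a subject frozen mid-motion admits no fixed-point completion", {
  net <- two_beh_net(signs = c(1, 1))
  sub <- subject_profile("s", c(beh01 = 3L, beh02 = 1L), net)
  for (tau in 1:3) {
    for (w in 1:2) {
      prog <- logic_program(net, tau = as.integer(tau), weight = as.integer(w))
      # demanding an exact stable match returns nothing ...
      exact <- impute_hidden(net, prog, sub, "fixed_point",
                             config = fit_config(max_departure = 0))
      expect_false(exact$feasible)
      # ... while the unconstrained imputation settles on the nearest fixed
      # point at a strictly positive departure, as brute force confirms
      near <- impute_hidden(net, prog, sub, "fixed_point")
      ref <- o_impute(net$nodes$id, sub$observed, o_edge_table(net, prog),
                      "fixed")
      expect_true(near$feasible)
      expect_gt(near$departure$absolute, 0)
      expect_equal(near$departure$absolute, as.integer(ref$dev))
    }
  }
})

test_that("the exhaustive fitter reproduces naive enumeration exactly", {
  for (seed in 1:12) {
    inst <- toy_instance(seed)
    for (mode in c("pred", "fixed")) {
      ref <- o_fit(inst$net, inst$subjects, tau_dom = 1:2, w_dom = 1:2,
                   mode = mode)
      cfg <- fit_config(tau_domain = 1:2, w_domain = 1:2,
                        consistency = if (mode == "pred") "has_predecessor"
                                      else "fixed_point",
                        search = "exhaustive", optima_cap = 5000L,
                        max_departure = if (is.finite(ref$best)) ref$best
                                        else 0)
      fit <- fit_program(inst$net, inst$subjects, config = cfg)
      if (!is.finite(ref$best)) {
        expect_equal(length(fit$programs), 0L)
        expect_equal(fit$feasible_count, 0)
        next
      }
      expect_equal(fit$departure$absolute, as.integer(ref$best))
      # identical optimal-program sets (feasibility budget set at the optimum)
      expect_setequal(vapply(fit$programs, o_prog_key, ""),
                      unique(ref$keys[ref$devs == ref$best]))
      expect_equal(fit$feasible_count, sum(ref$devs <= ref$best))
    }
  }
})

test_that("propagation never changes the exhaustive persistence verdict", {
  for (seed in 1:10) {
    inst <- toy_instance(100 + seed, n_subjects = 1)
    ref <- o_fit(inst$net, inst$subjects, tau_dom = 1:2, w_dom = 1:2,
                 mode = "fixed")
    cfg <- fit_config(tau_domain = 1:2, w_domain = 1:2,
                      search = "backtracking_propagation",
                      optima_cap = 5000L)
    pt <- persistence_test(inst$net, inst$subjects, config = cfg)
    expect_equal(pt$feasible, is.finite(ref$best) && ref$best == 0)
    expect_equal(pt$feasible_count, sum(ref$devs == 0))
  }
})

test_that("enlarging the parameter domains never worsens the optimum", {
  for (seed in 1:8) {
    inst <- toy_instance(200 + seed, max_edges = 4)
    devs <- vapply(list(1L, 1:2, 1:3), function(td) {
      cfg <- fit_config(tau_domain = td, w_domain = 1:2,
                        search = "exhaustive")
      fit_program(inst$net, inst$subjects, config = cfg)$departure$absolute
    }, 0L)
    expect_true(all(diff(devs) <= 0))
  }
})

test_that("local search matches the exhaustive optimum on toys", {
  for (seed in 1:6) {
    inst <- toy_instance(300 + seed, max_edges = 4)
    ex <- fit_program(inst$net, inst$subjects,
                      config = fit_config(search = "exhaustive",
                                          tau_domain = 1:2, w_domain = 1:2))
    ls <- fit_program(inst$net, inst$subjects,
                      config = fit_config(search = "local_search",
                                          tau_domain = 1:2, w_domain = 1:2,
                                          seed = seed, restarts = 30L))
    expect_equal(ls$departure$absolute, ex$departure$absolute)
  }
})

test_that("persistence splits rest-state subjects from forced-motion ones", {
  # subjects parked at the resting fixed point: every program preserves them
  net <- generate_network(3, 2, 6, seed = 4)
  rest_subjects <- lapply(1:3, function(i) {
    subject_profile(paste0("s", i), c(beh01 = 0L, beh02 = 0L), net)
  })
  cfg <- fit_config(search = "backtracking_propagation")
  pt <- persistence_test(net, rest_subjects, config = cfg)
  expect_true(pt$feasible)
  expect_gt(pt$feasible_count, 0)

  # a profile caught mid-motion (a maximal activator still pushing its
  # target upward) cannot persist under any program
  net2 <- two_beh_net(signs = c(1, 1))
  moving <- list(subject_profile("s1", c(beh01 = 3L, beh02 = 1L), net2))
  pt2 <- persistence_test(net2, moving, config = cfg)
  expect_false(pt2$feasible)
  expect_equal(pt2$feasible_count, 0)

  expect_error(persistence_test(net, list(), config = cfg), "at least one")
})

test_that("course prediction labels monotonicity correctly", {
  net <- two_beh_net(signs = c(1, -1))
  prog <- logic_program(net, tau = 1L, weight = 1L)
  # start at a fixed point: everything flat
  pc <- predict_course(net, prog, c(beh01 = 0L, beh02 = 0L))
  expect_true(all(pc$labels == "flat"))

  # a withdrawn activator pulse decays monotonically
  nodes <- data.frame(id = c("stress", "b1"),
                      kind = c("stressor", "behavioral"),
                      polarity = c("none", "severity"))
  casc <- logic_network(data.frame(source = "stress", target = "b1",
                                   sign = 1), nodes)
  pcasc <- logic_program(casc, tau = 1L, weight = 1L, tie_rule = "decay")
  pc2 <- predict_course(casc, pcasc, c(stress = 0L, b1 = 3L))
  expect_equal(unname(pc2$labels["b1"]), "decreasing")

  # a node on a cycle is non-monotone
  osc <- logic_network(data.frame(
    source = c("C", "C", "B", "A"), target = c("C", "A", "A", "B"),
    sign = c(1, 1, -1, 1)), allow_self_loops = TRUE)
  posc <- logic_program(osc, tau = c(1L, 1L, 1L, 2L),
                        weight = c(1L, 1L, 2L, 1L), tie_rule = "decay")
  pc3 <- predict_course(osc, posc, c(A = 2L, B = 0L, C = 3L))
  expect_equal(unname(pc3$labels["A"]), "non_monotone")
})

test_that("fits are deterministic under the configured seed", {
  b <- generate_study("small", seed = 9)
  cfg <- fit_config(search = "local_search", seed = 42)
  f1 <- fit_program(b$network, b$observed, config = cfg)
  f2 <- fit_program(b$network, b$observed, config = cfg)
  expect_identical(f1$programs[[1]]$tau, f2$programs[[1]]$tau)
  expect_identical(f1$programs[[1]]$weight, f2$programs[[1]]$weight)
  expect_identical(f1$departure, f2$departure)
})
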