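test_that("perception thresholds gate competing regulators as in the motif", {
  net <- motif_net()
  prog <- motif_prog(net)
  # inhibitor perceived at moderate severity, activator only at high severity
  st <- c(PTSD = 1L, Depression = 1L, MAOA = 1L)
  expect_equal(perceived_input("MAOA", st, net, prog), -1L)
  expect_equal(node_image("MAOA", st, net, prog), 0L)
  expect_false(is_fixed_point(st, net, prog))

  # raising the activator above its threshold flips the decision: the
  # heavier weight gives the activator more influence than the inhibitor
  st2 <- c(PTSD = 1L, Depression = 2L, MAOA = 1L)
  expect_equal(perceived_input("MAOA", st2, net, prog), 1L)
  expect_equal(node_image("MAOA", st2, net, prog), 2L)

  # all sources below threshold contribute nothing
  st0 <- c(PTSD = 0L, Depression = 0L, MAOA = 2L)
  expect_equal(perceived_input("MAOA", st0, net, prog), 0L)
  expect_equal(node_image("MAOA", st0, net, prog), 2L)  # hold
})

test_that("images saturate at the level bounds", {
  net <- two_beh_net(signs = c(1, -1))  # beh01 -> + beh02, beh02 -> - beh01
  prog <- logic_program(net, tau = 1L, weight = 1L)
  expect_equal(node_image("beh01", c(beh01 = 0L, beh02 = 3L), net, prog), 0L)
  expect_equal(node_image("beh02", c(beh01 = 3L, beh02 = 3L), net, prog), 3L)
  expect_equal(node_image("beh01", c(beh01 = 2L, beh02 = 1L), net, prog), 1L)
})

test_that("the synchronous step updates all nodes at once", {
  net <- two_beh_net(signs = c(1, -1))
  prog <- logic_program(net, tau = 1L, weight = 1L)
  expect_equal(step_state(c(beh01 = 3L, beh02 = 0L), net, prog),
               c(beh01 = 3L, beh02 = 1L))
  # a fixed point steps onto itself
  fp <- c(beh01 = 0L, beh02 = 0L)
  expect_equal(step_state(fp, net, prog), fp)
})

test_that("the asynchronous step is deterministic under a seed", {
  net <- rand_net(n = 5, n_edges = 8, seed = 3)
  prog <- sample_program(net, seed = 3, update_scheme = "asynchronous")
  st <- rand_state(net)
  set.seed(99)
  a <- step_state(st, net, prog)
  set.seed(99)
  b <- step_state(st, net, prog)
  expect_identical(a, b)
  # exactly one node changes (or none, at a fixed point)
  expect_lte(sum(a != st), 1L)
})

test_that("trajectories classify fixed points and cycles as the full state graph does", {
  net <- two_beh_net(signs = c(1, -1))
  # decay ties let the negative feedback loop oscillate
  prog <- logic_program(net, tau = 1L, weight = 1L, tie_rule = "decay")
  ed <- o_edge_table(net, prog)

  # oracle: follow the exhaustive transition map from (3, 0)
  seen <- list()
  st <- c(beh01 = 3L, beh02 = 0L)
  repeat {
    key <- paste(st, collapse = ",")
    if (key %in% names(seen)) break
    seen[[key]] <- st
    st <- setNames(as.integer(unlist(o_step(st, ed, tie = "decay"))),
                   names(st))
  }
  first <- match(paste(st, collapse = ","), names(seen))
  o_period <- length(seen) - first + 1L

  traj <- simulate_trajectory(c(beh01 = 3L, beh02 = 0L), net, prog,
                              max_steps = 100)
  expect_equal(traj$period, o_period)
  expect_equal(traj$type, if (o_period == 1L) "fixed_point" else "cycle")
  expect_equal(traj$transient_length, first - 1L)

  # an engineered relaxation oscillator: a self-sustaining driver C pushes A
  # up, A recruits its own inhibitor B with a lag (B only perceives A at
  # high level and carries the heavier weight), and decay ties pull B back
  # down once A has fallen -- the hallmark of delayed negative feedback
  osc <- logic_network(data.frame(
    source = c("C", "C", "B", "A"), target = c("C", "A", "A", "B"),
    sign = c(1, 1, -1, 1)), allow_self_loops = TRUE)
  posc <- logic_program(osc, tau = c(1L, 1L, 1L, 2L),
                        weight = c(1L, 1L, 2L, 1L), tie_rule = "decay")
  tro <- simulate_trajectory(c(A = 2L, B = 0L, C = 3L), osc, posc,
                             max_steps = 200)
  expect_equal(tro$type, "cycle")
  expect_gte(tro$period, 2L)
  # every attractor state maps onto the next under the oracle step
  edo <- o_edge_table(osc, posc)
  att <- tro$attractor
  for (r in seq_len(nrow(att))) {
    nxt <- att[(r %% nrow(att)) + 1L, ]
    cur <- setNames(as.integer(att[r, ]), colnames(att))
    expect_equal(unname(as.integer(unlist(o_step(cur, edo, "decay"))[colnames(att)])),
                 unname(nxt))
  }

  # starting on a fixed point: zero transient, period one
  hold <- logic_program(net, tau = 1L, weight = 1L)
  fp <- c(beh01 = 0L, beh02 = 0L)
  tr2 <- simulate_trajectory(fp, net, hold, max_steps = 10)
  expect_equal(tr2$transient_length, 0L)
  expect_equal(tr2$type, "fixed_point")
  expect_equal(unname(tr2$attractor[1, ]), unname(fp))

  # a node with no in-edges holds any level: everything is a fixed point
  iso <- logic_network(data.frame(source = "A", target = "B", sign = 1))
  piso <- logic_program(iso, tau = 3L, weight = 1L)
  for (l in 0:3) {
    expect_true(is_fixed_point(c(A = l, B = l), iso, piso))
  }

  expect_error(simulate_trajectory(c(beh01 = 3L, beh02 = 0L), net, prog,
                                   max_steps = 1),
               "horizon exceeded")
})

test_that("predecessor enumeration matches forward-map inversion", {
  for (seed in 1:40) {
    net <- rand_net(n = sample(2:4, 1), seed = seed)
    prog <- sample_program(net, tie_rule = sample(c("hold", "decay"), 1))
    st <- rand_state(net)
    ours <- state_predecessors(st, net, prog)
    ref <- o_predecessors(st, o_edge_table(net, prog),
                          tie = attr(prog, "tie_rule"))
    expect_equal(nrow(ours), nrow(ref))
    if (nrow(ref)) {
      expect_setequal(apply(ours, 1, paste, collapse = ","),
                      apply(ref, 1, paste, collapse = ","))
    }
    # fixed-point equivalences: p fixed <=> step(p) = p <=> p among its
    # own predecessors
    fp <- is_fixed_point(st, net, prog)
    expect_equal(fp, all(step_state(st, net, prog) == st))
    expect_equal(fp,
                 paste(st, collapse = ",") %in%
                   apply(ours, 1, paste, collapse = ","))
  }
})

test_that("a forced-motion state is garden-of-eden", {
  # beh01 clamped at 3 activates beh02 under every threshold, so any
  # predecessor must push beh02 upward: (3, 0) cannot be reached
  net <- two_beh_net(signs = c(1, 1))
  prog <- logic_program(net, tau = 1L, weight = 1L)
  preds <- state_predecessors(c(beh01 = 3L, beh02 = 0L), net, prog,
                              clamps = c(beh01 = 3L))
  expect_equal(nrow(preds), 0L)
})

test_that("candidate-set predecessor mode filters exactly", {
  net <- rand_net(n = 4, n_edges = 6, seed = 8)
  prog <- sample_program(net, seed = 8)
  st <- rand_state(net)
  all_states <- o_all_states(net$nodes$id)
  via_cand <- state_predecessors(st, net, prog, candidates = all_states)
  direct <- state_predecessors(st, net, prog)
  expect_equal(nrow(via_cand), nrow(direct))
})

test_that("oversized state spaces demand a candidate set", {
  net <- generate_network(10, 4, 16, seed = 2)
  prog <- sample_program(net, seed = 2)
  st <- setNames(rep(0L, 15), net$nodes$id)
  expect_error(state_predecessors(st, net, prog, budget = 4^6),
               "candidate")
})

test_that("gating is monotone: raising a source only switches an edge on", {
  for (seed in 1:60) {
    net <- rand_net(n = sample(3:5, 1), seed = seed)
    prog <- sample_program(net)
    st <- rand_state(net)
    for (e in seq_len(nrow(net$edges))) {
      src <- net$edges$source[e]
      tgt <- net$edges$target[e]
      if (st[[src]] >= 3L) next
      st_hi <- st
      st_hi[[src]] <- st[[src]] + 1L
      delta <- perceived_input(tgt, st_hi, net, prog) -
        perceived_input(tgt, st, net, prog)
      # contributions only ever switch on with the edge's own sign
      edges_from <- net$edges$source == src & net$edges$target == tgt
      w <- prog$weight[edges_from] * prog$sign[edges_from]
      expect_true(delta == 0 || delta == sum(w) ||
                    delta %in% (prog$sign[edges_from] * prog$weight[edges_from]))
    }
  }
})

test_that("engine and naive oracle agree on random triples", {
  for (seed in 1:120) {
    net <- rand_net(n = sample(2:6, 1), seed = 1000 + seed)
    tie <- sample(c("hold", "decay"), 1)
    prog <- sample_program(net, tie_rule = tie)
    st <- rand_state(net)
    ed <- o_edge_table(net, prog)
    expect_equal(unname(step_state(st, net, prog)),
                 unname(as.integer(unlist(o_step(st, ed, tie))[names(st)])))
    nd <- sample(net$nodes$id, 1)
    expect_equal(perceived_input(nd, st, net, prog),
                 o_perceived(nd, st, ed))
  }
})
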