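test_that("a minimal edge list builds the smallest legal cycle", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,sign",
               "A,B,activate", "B,C,inhibit", "C,A,activate"), f)
  net <- read_network(f)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  expect_equal(validate_feedback_closure(net), character(0))
  expect_equal(sort(net$edges$sign), c(-1L, 1L, 1L))
})

test_that("duplicate same-sign rows collapse additively", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,sign,n_citations",
               "A,B,activate,3", "B,C,inhibit,2", "C,A,activate,1",
               "A,B,activate,4"), f)
  net <- read_network(f, collapse = "sum")
  ab <- net$edges[net$edges$source == "A" & net$edges$target == "B", ]
  expect_equal(ab$n_citations, 7L)
  net_max <- read_network(f, collapse = "max")
  ab <- net_max$edges[net_max$edges$source == "A" & net_max$edges$target == "B", ]
  expect_equal(ab$n_citations, 4L)
})

test_that("conflicting signs for one ordered pair are a hard error naming it", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,sign", "A,B,activate", "A,B,inhibit"), f)
  expect_error(read_network(f), "\\(A, B\\)")
})

test_that("edges referencing undeclared nodes are rejected", {
  nodes <- data.frame(id = c("A", "B"), kind = "molecular", polarity = "none")
  expect_error(
    logic_network(data.frame(source = c("A", "B"), target = c("B", "Z"),
                             sign = 1), nodes),
    "unknown node.*Z")
})

test_that("stressor in-edges and misplaced function polarity are rejected", {
  nodes <- data.frame(id = c("S", "A", "B"),
                      kind = c("stressor", "molecular", "molecular"),
                      polarity = "none")
  expect_error(
    logic_network(data.frame(source = c("A", "B"), target = c("B", "S"),
                             sign = 1), nodes),
    "out-edges only")
  nodes2 <- data.frame(id = c("A", "B"), kind = "molecular",
                       polarity = c("function", "none"))
  expect_error(
    logic_network(data.frame(source = "A", target = "B", sign = 1), nodes2),
    "function")
})

test_that("feedback closure flags chain nodes but exempts the stressor", {
  chain <- logic_network(data.frame(source = c("A", "B"),
                                    target = c("B", "C"), sign = 1))
  expect_setequal(validate_feedback_closure(chain), c("A", "B", "C"))

  nodes <- data.frame(id = c("A", "B", "C", "S"),
                      kind = c(rep("molecular", 3), "stressor"),
                      polarity = "none")
  cyc <- logic_network(data.frame(source = c("A", "B", "C", "S"),
                                  target = c("B", "C", "A", "A"),
                                  sign = 1), nodes)
  expect_equal(validate_feedback_closure(cyc), character(0))
})

test_that("feedback closure agrees with a depth-first cycle oracle", {
  for (seed in 1:60) {
    net <- rand_net(n = sample(3:6, 1), seed = seed)
    expected <- setdiff(net$nodes$id,
                        o_cycle_nodes(net$edges, net$nodes$id))
    expect_setequal(validate_feedback_closure(net), expected)
  }
})

test_that("evidence summary matches hand counts and a sort-based median", {
  net <- logic_network(data.frame(source = c("A", "B", "C"),
                                  target = c("B", "C", "A"), sign = 1,
                                  n_citations = c(1, 9, 200)))
  ev <- summarize_evidence(net)
  expect_equal(ev$median_citations, 9)
  expect_equal(ev$n_ge5, 2L)
  expect_equal(ev$n_eq1, 1L)

  net2 <- logic_network(data.frame(source = c("A", "B"), target = c("B", "A"),
                                   sign = 1, n_citations = c(7, 7)))
  ev2 <- summarize_evidence(net2)
  expect_equal(ev2$median_citations, 7)
  expect_equal(ev2$n_ge5, 2L)
  expect_equal(ev2$n_eq1, 0L)

  net0 <- logic_network(data.frame(source = "A", target = "B", sign = 1,
                                   n_citations = 0))
  expect_error(summarize_evidence(net0), "no edges")

  for (seed in 1:25) {
    set.seed(seed)
    cit <- sample(1:300, sample(3:20, 1), replace = TRUE)
    src <- paste0("a", seq_along(cit))
    net <- logic_network(data.frame(source = src,
                                    target = c(src[-1], src[1]),
                                    sign = 1, n_citations = cit))
    sorted <- sort(cit)
    m <- length(sorted)
    med <- if (m %% 2 == 1) sorted[(m + 1) / 2]
           else (sorted[m / 2] + sorted[m / 2 + 1]) / 2
    expect_equal(summarize_evidence(net)$median_citations, med)
  }
})

test_that("edge-csv round-trips randomized networks exactly", {
  for (seed in 1:100) {
    net <- rand_net(n = sample(3:7, 1), n_beh = sample(0:2, 1), seed = seed)
    f <- tempfile(fileext = ".csv")
    nf <- tempfile(fileext = ".csv")
    write_network(net, f, node_table_path = nf)
    back <- read_network(f, node_table = nf)
    expect_equal(back$edges[order(back$edges$source, back$edges$target), ],
                 net$edges[order(net$edges$source, net$edges$target), ],
                 ignore_attr = TRUE)
    expect_equal(back$nodes[order(back$nodes$id), ],
                 net$nodes[order(net$nodes$id), ], ignore_attr = TRUE)
    unlink(c(f, nf))
  }
})

test_that("SIF export keeps the signed topology and round-trips", {
  net <- logic_network(data.frame(source = c("A", "B", "C"),
                                  target = c("B", "C", "A"),
                                  sign = c(1, -1, 1)))
  f <- withr::local_tempfile(fileext = ".sif")
  write_network(net, f, format = "sif")
  expect_equal(readLines(f)[1], "A\tactivate\tB")
  back <- read_network(f)
  expect_equal(back$edges[, c("source", "target", "sign")],
               net$edges[, c("source", "target", "sign")])
})

test_that("an empty network cannot be written", {
  net <- logic_network(data.frame(source = "A", target = "B", sign = 1))
  net$edges <- net$edges[0, ]
  expect_error(write_network(net, tempfile()), "empty")
})
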