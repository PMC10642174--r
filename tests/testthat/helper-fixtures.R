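# Programmatic fixtures shared across the suite.

# A small random network: n nodes, random distinct directed edges (no self
# loops). By default the first `n_beh` nodes are behavioral.
rand_net <- function(n = 4, n_edges = NULL, n_beh = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("n", seq_len(n))
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  if (is.null(n_edges)) n_edges <- sample(seq_len(min(8, nrow(pairs))), 1)
  ed <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
  ed$sign <- sample(c(1L, -1L), n_edges, replace = TRUE)
  ed$n_citations <- sample(0:30, n_edges, replace = TRUE)
  kind <- c(rep("behavioral", n_beh), rep("molecular", n - n_beh))
  nodes <- data.frame(id = ids, kind = kind,
                      polarity = ifelse(kind == "behavioral", "severity",
                                        "none"),
                      stringsAsFactors = FALSE)
  logic_network(ed, nodes)
}

rand_state <- function(net) {
  setNames(sample(0:3, nrow(net$nodes), replace = TRUE), net$nodes$id)
}

# A random toy fit instance: small network with observed behavioral nodes
# and random observed profiles.
toy_instance <- function(seed, n_beh = 2, max_nodes = 5, max_edges = 5,
                         n_subjects = 2) {
  set.seed(seed)
  n <- sample(3:max_nodes, 1)
  net <- rand_net(n = n, n_edges = sample(2:max_edges, 1), n_beh = n_beh,
                  seed = seed)
  beh <- net$nodes$id[net$nodes$kind == "behavioral"]
  subjects <- lapply(seq_len(n_subjects), function(i) {
    subject_profile(paste0("s", i),
                    setNames(sample(0:3, length(beh), TRUE), beh), net)
  })
  list(net = net, subjects = subjects)
}

# Two behavioral constructs wired head-to-head; handy for forced-motion cases.
two_beh_net <- function(signs = c(1, 1)) {
  logic_network(
    data.frame(source = c("beh01", "beh02"), target = c("beh02", "beh01"),
               sign = signs),
    nodes = data.frame(id = c("beh01", "beh02"), kind = "behavioral",
                       polarity = "severity", stringsAsFactors = FALSE))
}

# The two-regulator motif used throughout: one inhibitor perceived at
# moderate severity (tau 1), one activator perceived only at high severity
# (tau 2) but with the larger weight.
motif_net <- function() {
  logic_network(
    data.frame(source = c("PTSD", "Depression", "MAOA", "MAOA"),
               target = c("MAOA", "MAOA", "PTSD", "Depression"),
               sign = c(-1, 1, 1, 1)),
    nodes = data.frame(id = c("PTSD", "Depression", "MAOA"),
                       kind = c("behavioral", "behavioral", "molecular"),
                       polarity = c("severity", "severity", "none"),
                       stringsAsFactors = FALSE))
}

motif_prog <- function(net = motif_net()) {
  # edges in net$edges row order: PTSD->MAOA, Depression->MAOA, MAOA->PTSD,
  # MAOA->Depression
  logic_program(net, tau = c(1L, 2L, 3L, 3L), weight = c(1L, 2L, 1L, 1L))
}
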