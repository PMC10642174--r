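#' Draw heavy-tailed literature-evidence counts
#'
#' Citation counts per interaction follow a discretized lognormal,
#' `max(1, round(exp(N(log 9, 1.8^2))))`: median about 9 citations, roughly
#' 15% of edges supported by a single publication and a few percent beyond
#' 125 — the qualitative evidence profile of large text-mined regulatory
#' networks.
#'
#' @param m number of draws.
#' @param meanlog,sdlog lognormal parameters.
#' @return integer vector of positive counts.
#' @export
sample_citation_counts <- function(m, meanlog = log(9), sdlog = 1.8) {
  pmax(1L, as.integer(round(exp(stats::rnorm(m, meanlog, sdlog)))))
}

#' Generate a paper-shaped random regulatory network
#'
#' Builds a directed signed graph over `n_molecular` molecular,
#' `n_behavioral` behavioral and one exogenous stressor node in which every
#' non-stressor node lies on a directed cycle by construction: a random
#' spanning cycle over the non-stressor nodes is laid down first, the
#' stressor receives at least one out-edge, and the remaining edge budget is
#' filled with distinct random edges (never into the stressor, no
#' self-loops). Edge signs are inhibitory with probability
#' `inhibitor_fraction` and every edge draws a citation count from
#' [sample_citation_counts()].
#'
#' @param n_molecular,n_behavioral node counts (the stressor is added on
#'   top).
#' @param n_edges total directed edges; must be at least
#'   `n_molecular + n_behavioral + 1` (spanning cycle plus the stressor
#'   out-edge) and at most `(N-1)^2` for `N` total nodes.
#' @param inhibitor_fraction probability that an edge is inhibitory.
#' @param seed optional integer seed.
#' @return a validated `logic_network` with empty
#'   [validate_feedback_closure()] violations.
#' @export
generate_network <- function(n_molecular = 29L, n_behavioral = 9L,
                             n_edges = 273L, inhibitor_fraction = 0.3,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_core <- n_molecular + n_behavioral
  n <- n_core + 1L
  if (n_edges < n_core + 1L) {
    stop("edge budget infeasible: need at least ", n_core + 1L,
         " edges to close all feedback loops")
  }
  if (n_edges > (n - 1L)^2) {
    stop("edge budget exceeds the ", (n - 1L)^2, " admissible ordered pairs")
  }
  mol <- sprintf("mol%02d", seq_len(n_molecular))
  beh <- sprintf("beh%02d", seq_len(n_behavioral))
  core <- c(mol, beh)
  stressor <- "stress"
  nodes <- data.frame(
    id = c(core, stressor),
    kind = c(rep("molecular", n_molecular), rep("behavioral", n_behavioral),
             "stressor"),
    polarity = c(rep("none", n_molecular), rep("severity", n_behavioral),
                 "none"),
    stringsAsFactors = FALSE)

  perm <- sample(core)
  edges <- data.frame(source = perm, target = c(perm[-1L], perm[1L]),
                      stringsAsFactors = FALSE)
  edges <- rbind(edges,
                 data.frame(source = stressor, target = sample(core, 1L),
                            stringsAsFactors = FALSE))
  all_pairs <- expand.grid(source = c(core, stressor), target = core,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
  key <- function(d) paste(d$source, d$target, sep = "\r")
  pool <- all_pairs[!key(all_pairs) %in% key(edges), ]
  extra <- n_edges - nrow(edges)
  if (extra > 0L) {
    pick <- sample.int(nrow(pool), extra)
    edges <- rbind(edges, pool[pick, ])
  }
  edges$sign <- ifelse(stats::runif(nrow(edges)) < inhibitor_fraction,
                       -1L, 1L)
  edges$n_citations <- sample_citation_counts(nrow(edges))
  rownames(edges) <- NULL
  net <- logic_network(edges, nodes)
  stopifnot(length(validate_feedback_closure(net)) == 0L)
  net
}

#' Simulate subject snapshots from a planted logic program
#'
#' Every subject starts at the resting control fixed point (the all-zero
#' engine state), receives the stressor pulse, and evolves under the planted
#' program's synchronous dynamics. One snapshot time per subject is drawn
#' uniformly from `snapshot_window` (in steps after pulse onset); the
#' subject's observed profile is the behavioral restriction of the state at
#' that time, optionally jittered by one level with probability
#' `noise_rate` per construct (clamped to 0..3). Ground truth (full states
#' and snapshot times) is retained, so parameter- and hidden-state recovery
#' can be scored exactly.
#'
#' @param net a `logic_network` (with a stressor node for a nontrivial
#'   response).
#' @param prog the planted `logic_program`.
#' @param n_subjects number of subjects.
#' @param stressor_pulse `c(level, duration)` of the exogenous pulse.
#' @param snapshot_window inclusive integer range of snapshot times (steps
#'   since pulse onset).
#' @param noise_rate per-construct probability of a one-level observation
#'   jitter.
#' @param seed optional integer seed; the bundle is bit-for-bit reproducible
#'   from the same seed and arguments.
#' @param horizon trajectory horizon.
#' @return object of class `study_bundle`: list with `network`,
#'   `truth_program`, `truth_states` (matrix), `snapshot_times`, `observed`
#'   (list of `subject_profile`), `control`, `trajectory` (the pulse
#'   response), `seed`.
#' @export
simulate_subjects <- function(net, prog, n_subjects = 6L,
                              stressor_pulse = c(level = 3L, duration = 4L),
                              snapshot_window = c(2L, 12L), noise_rate = 0,
                              seed = NULL, horizon = 200L) {
  if (!is.null(seed)) set.seed(seed)
  ids <- net$nodes$id
  rest <- setNames(rep(0L, length(ids)), ids)
  if (!is_fixed_point(rest, net, prog)) {
    stop("invalid planted system: the resting control state is not a fixed point")
  }
  pulse <- c(level = as.integer(stressor_pulse[[1]]),
             duration = as.integer(stressor_pulse[[2]]))
  traj <- .pulse_trajectory(net, prog, pulse, horizon)
  t_max <- nrow(traj) - 1L  # row 1 is t = 0
  if (snapshot_window[2] > t_max) {
    # past the recorded horizon the system cycles on its attractor
    period <- attr(traj, "period")
    transient_end <- attr(traj, "transient_end")
    att <- traj[(nrow(traj) - period + 1L):nrow(traj), , drop = FALSE]
    need <- snapshot_window[2] - t_max
    traj <- rbind(traj, att[((seq_len(need) - 1L) %% period) + 1L, ,
                            drop = FALSE])
    attr(traj, "period") <- period
    attr(traj, "transient_end") <- transient_end
  }
  if (snapshot_window[1] < 0L) stop("snapshot_window must be nonnegative")
  window_steps <- seq(snapshot_window[1], snapshot_window[2])
  times <- window_steps[sample.int(length(window_steps), n_subjects,
                                   replace = TRUE)]
  beh <- ids[net$nodes$kind == "behavioral"]
  truth <- traj[times + 1L, , drop = FALSE]
  rownames(truth) <- sprintf("subj%02d", seq_len(n_subjects))
  observed <- lapply(seq_len(n_subjects), function(s) {
    lev <- truth[s, beh]
    jit <- stats::runif(length(lev)) < noise_rate
    if (any(jit)) {
      dir <- sample(c(-1L, 1L), sum(jit), replace = TRUE)
      lev[jit] <- pmin(3L, pmax(0L, lev[jit] + dir))
    }
    subject_profile(sprintf("subj%02d", s), setNames(as.integer(lev), beh),
                    net)
  })
  structure(list(network = net, truth_program = prog,
                 truth_states = truth, snapshot_times = times,
                 observed = observed,
                 control = control_profile(net),
                 trajectory = traj, pulse = pulse, seed = seed),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d nodes, %d edges; %d subjects sampled at steps %s\n",
              nrow(x$network$nodes), nrow(x$network$edges),
              length(x$observed), paste(x$snapshot_times, collapse = ",")))
  invisible(x)
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper: network, planted program, and subject snapshots in
#' one reproducible call. The `"paper_shape"` preset matches the study
#' dimensions this package is organized around (29 molecular + 9 behavioral
#' nodes + 1 stressor, 273 edges, 6 subjects); `"small"` is a 10-node
#' variant (6 molecular + 3 behavioral + stressor, 14 edges) used for
#' exhaustive validation.
#'
#' @param preset `"paper_shape"` or `"small"`.
#' @param seed integer seed driving every random choice.
#' @param noise_rate observation jitter probability.
#' @param snapshot_window overrides the preset snapshot window when given.
#' @return a `study_bundle`.
#' @export
generate_study <- function(preset = c("paper_shape", "small"), seed = 1L,
                           noise_rate = 0, snapshot_window = NULL) {
  preset <- match.arg(preset)
  set.seed(seed)
  if (preset == "paper_shape") {
    net <- generate_network(29L, 9L, 273L, inhibitor_fraction = 0.3)
    pulse <- c(level = 3L, duration = 4L)
    window <- snapshot_window %||% c(2L, 12L)
  } else {
    net <- generate_network(6L, 3L, 14L, inhibitor_fraction = 0.3)
    pulse <- c(level = 3L, duration = 3L)
    window <- snapshot_window %||% c(1L, 8L)
  }
  prog <- sample_program(net, tau_domain = 1:3, w_domain = 1:2)
  simulate_subjects(net, prog, n_subjects = 6L, stressor_pulse = pulse,
                    snapshot_window = window, noise_rate = noise_rate)
}

#' Write a study bundle to plain-text files
#'
#' Emits `network.csv` + `nodes.csv` (see [write_network()]),
#' `profiles.csv` (see [write_profiles()]) and `truth.json` (planted
#' program, snapshot times, full truth states).
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(bundle$network, file.path(dir, "network.csv"),
                node_table_path = file.path(dir, "nodes.csv"))
  write_profiles(bundle$observed, file.path(dir, "profiles.csv"))
  truth <- list(program = as.data.frame(bundle$truth_program),
                tie_rule = attr(bundle$truth_program, "tie_rule"),
                snapshot_times = bundle$snapshot_times,
                truth_states = as.data.frame(bundle$truth_states),
                pulse = as.list(bundle$pulse), seed = bundle$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
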