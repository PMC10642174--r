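#' Perceived input of a node
#'
#' The signed, weighted sum over in-edges whose source is activated at or
#' above the edge's perception threshold:
#' `s = sum over in-edges e of sign(e) * w(e) * [state(source(e)) >= tau(e)]`.
#' Sources below threshold are imperceptible and contribute nothing.
#'
#' @param node node id.
#' @param state full state, a named integer vector of levels 0..3.
#' @param net a `logic_network`.
#' @param prog a `logic_program`.
#' @return signed integer.
#' @export
perceived_input <- function(node, state, net, prog) {
  state <- .as_state(state, net)
  if (!node %in% net$nodes$id) stop("unknown node: ", node)
  al <- .align_program(net, prog)
  ine <- which(net$edges$target == node)
  if (!length(ine)) return(0L)
  src <- net$edges$source[ine]
  as.integer(sum(net$edges$sign[ine] * al$w[ine] *
                   (state[src] >= al$tau[ine])))
}

#' Next-iteration level of a node
#'
#' A node moves one level toward the sign of its perceived input, clamped to
#' 0..3. A balanced input (`s = 0`) keeps the level under the `"hold"` tie
#' rule or relaxes it one level toward 0 under `"decay"`. Clamped nodes
#' (e.g. the exogenous stressor during a pulse) take their clamp value.
#'
#' @inheritParams perceived_input
#' @param clamps optional named vector of levels for externally held nodes.
#' @return level in 0..3.
#' @export
node_image <- function(node, state, net, prog, clamps = NULL) {
  st <- step_state(state, net, prog, clamps = clamps, scheme = "synchronous")
  st[[node]]
}

.images <- function(state, net, prog, clamps = NULL) {
  idx <- .net_idx(net)
  al <- .align_program(net, prog)
  st <- .as_state(state, net)
  out <- cpp_images(unname(st), idx$esrc0, idx$etgt0, idx$esign,
                    al$tau, al$w, .tie_code(attr(prog, "tie_rule")),
                    .clamp_vec(net, clamps))
  setNames(as.integer(out), idx$ids)
}

#' Advance the network by one update
#'
#' Synchronous updates replace every node by its image simultaneously;
#' asynchronous updates pick one non-quiescent node (image differs from
#' level) uniformly at random — seed the R RNG for reproducibility — and
#' update only that node.
#'
#' @inheritParams node_image
#' @param state full state, named integer vector of levels 0..3.
#' @param scheme `"synchronous"`, `"asynchronous"`, or `NULL` to use the
#'   program's update scheme.
#' @return the successor state.
#' @export
step_state <- function(state, net, prog, clamps = NULL, scheme = NULL) {
  scheme <- scheme %||% attr(prog, "update_scheme") %||% "synchronous"
  img <- .images(state, net, prog, clamps)
  if (scheme == "synchronous") return(img)
  st <- .as_state(state, net)
  active <- which(img != st)
  if (!length(active)) return(st)
  pick <- if (length(active) == 1L) active else sample(active, 1L)
  st[pick] <- img[pick]
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Is a state a fixed point?
#'
#' True iff every node's image equals its current level, i.e. the state maps
#' to itself under the synchronous update.
#'
#' @inheritParams step_state
#' @return logical.
#' @export
is_fixed_point <- function(state, net, prog, clamps = NULL) {
  st <- .as_state(state, net)
  all(.images(st, net, prog, clamps) == st)
}

#' Simulate a trajectory to its attractor
#'
#' Iterates [step_state()] from `state0` until a previously visited state
#' recurs, then classifies the attractor as a fixed point (period 1) or a
#' cycle (period >= 2). Under the synchronous scheme the dynamics are a
#' deterministic total function, so every trajectory enters an attractor
#' within `4^N` steps; attractor classification is only meaningful for the
#' synchronous scheme.
#'
#' @inheritParams step_state
#' @param state0 initial full state.
#' @param max_steps horizon; an error is raised if no state repeats in time.
#' @return object of class `trajectory`: list with `states` (matrix, one row
#'   per visited state including `state0`), `transient_length`, `period`,
#'   `attractor` (matrix of the attractor states) and `type`
#'   (`"fixed_point"` or `"cycle"`).
#' @export
simulate_trajectory <- function(state0, net, prog, clamps = NULL,
                                max_steps = 1000L, scheme = NULL) {
  if (max_steps < 1L) stop("max_steps must be >= 1")
  st <- .as_state(state0, net)
  states <- list(st)
  seen <- new.env(parent = emptyenv())
  assign(paste(st, collapse = ","), 1L, envir = seen)
  for (t in seq_len(max_steps)) {
    st <- step_state(st, net, prog, clamps = clamps, scheme = scheme)
    key <- paste(st, collapse = ",")
    first <- seen[[key]]
    if (!is.null(first)) {
      mat <- do.call(rbind, states)
      colnames(mat) <- net$nodes$id
      period <- length(states) - first + 1L
      att <- mat[first:length(states), , drop = FALSE]
      return(structure(list(states = mat,
                            transient_length = first - 1L,
                            period = period,
                            attractor = att,
                            type = if (period == 1L) "fixed_point" else "cycle"),
                       class = "trajectory"))
    }
    states[[length(states) + 1L]] <- st
    assign(key, length(states), envir = seen)
  }
  stop("horizon exceeded: no state repeated within ", max_steps, " steps")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d states; transient %d; %s (period %d)\n",
              nrow(x$states), x$transient_length, x$type, x$period))
  invisible(x)
}

#' Enumerate the dynamical predecessors of a state
#'
#' All states `y` with synchronous `step(y) == state`. An empty result means
#' the state is a garden-of-eden state: it cannot be a snapshot of an
#' ongoing response. The state space has size `4^N`; beyond the budget an
#' explicit candidate set must be supplied.
#'
#' @inheritParams step_state
#' @param candidates optional matrix (rows = states) to restrict the search
#'   to; required when `4^N` exceeds `budget`.
#' @param budget maximum number of search-node expansions.
#' @return matrix with one row per predecessor state (possibly 0 rows).
#' @export
state_predecessors <- function(state, net, prog, clamps = NULL,
                               candidates = NULL, budget = 4^12) {
  st <- .as_state(state, net)
  idx <- .net_idx(net)
  if (!is.null(candidates)) {
    keep <- apply(candidates, 1L, function(y) {
      all(.images(setNames(as.integer(y), idx$ids), net, prog, clamps) == st)
    })
    out <- candidates[keep, , drop = FALSE]
    colnames(out) <- idx$ids
    return(out)
  }
  if (4^idx$n > budget) {
    stop("state space 4^", idx$n, " exceeds the search budget; ",
         "supply a candidate set via `candidates`")
  }
  al <- .align_program(net, prog)
  res <- cpp_predecessors(unname(st), idx$esrc0, idx$etgt0, idx$esign,
                          al$tau, al$w, .tie_code(attr(prog, "tie_rule")),
                          .clamp_vec(net, clamps),
                          .dfs_order(idx, seq_len(idx$n) - 1L),
                          budget, 65536L)
  if (res$truncated) stop("predecessor search exceeded its budget")
  out <- res$preds
  colnames(out) <- idx$ids
  out
}
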