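# Naive, independently written reference implementations used to cross-check
# the engine, the fitter and the statistics. These deliberately use plain R
# loops over explicit enumerations and share no code with the package
# internals.

# edge table: data.frame(source, target, sign, tau, weight)
o_edge_table <- function(net, prog) {
  data.frame(source = prog$source, target = prog$target, sign = prog$sign,
             tau = prog$tau, weight = prog$weight, stringsAsFactors = FALSE)
}

o_perceived <- function(node, state, ed) {
  s <- 0
  for (r in seq_len(nrow(ed))) {
    if (ed$target[r] == node && state[[ed$source[r]]] >= ed$tau[r]) {
      s <- s + ed$sign[r] * ed$weight[r]
    }
  }
  s
}

o_image <- function(node, state, ed, tie = "hold", clamps = NULL) {
  if (!is.null(clamps) && node %in% names(clamps)) return(clamps[[node]])
  s <- o_perceived(node, state, ed)
  lvl <- state[[node]]
  if (s > 0) return(min(lvl + 1, 3))
  if (s < 0) return(max(lvl - 1, 0))
  if (tie == "hold") lvl else max(lvl - 1, 0)
}

o_step <- function(state, ed, tie = "hold", clamps = NULL) {
  out <- state
  for (nd in names(state)) out[[nd]] <- o_image(nd, state, ed, tie, clamps)
  out
}

# all 4^n states over the given node ids, one row per state
o_all_states <- function(ids) {
  g <- as.matrix(expand.grid(rep(list(0:3), length(ids))))
  colnames(g) <- ids
  g
}

o_predecessors <- function(state, ed, tie = "hold", clamps = NULL) {
  ids <- names(state)
  all <- o_all_states(ids)
  keep <- logical(nrow(all))
  for (r in seq_len(nrow(all))) {
    y <- setNames(as.integer(all[r, ]), ids)
    if (!is.null(clamps) && any(y[names(clamps)] != unlist(clamps))) next
    keep[r] <- all(unlist(o_step(y, ed, tie, clamps)) == unlist(state))
  }
  all[keep, , drop = FALSE]
}

# synchronous images of every row of a state matrix at once (vectorized but
# still a direct transcription of the update rule)
o_step_all <- function(S, ed, tie = "hold") {
  X <- S
  for (nd in colnames(S)) {
    s <- numeric(nrow(S))
    for (r in seq_len(nrow(ed))) {
      if (ed$target[r] == nd) {
        s <- s + ed$sign[r] * ed$weight[r] * (S[, ed$source[r]] >= ed$tau[r])
      }
    }
    lvl <- S[, nd]
    up <- pmin(lvl + 1, 3)
    down <- pmax(lvl - 1, 0)
    hold <- if (tie == "hold") lvl else down
    X[, nd] <- ifelse(s > 0, up, ifelse(s < 0, down, hold))
  }
  X
}

# minimum departure over consistent full states; returns list(dev, states)
o_impute <- function(ids, observed, ed, mode = c("pred", "fixed"),
                     tie = "hold") {
  mode <- match.arg(mode)
  S <- o_all_states(ids)
  X <- o_step_all(S, ed, tie)
  if (mode == "fixed") {
    keep <- rowSums(X != S) == 0
    if (!any(keep)) return(list(dev = NA, states = NULL))
    X <- S[keep, , drop = FALSE]
  }
  dev <- rowSums(abs(X[, names(observed), drop = FALSE] -
                       matrix(observed, nrow(X), length(observed),
                              byrow = TRUE)))
  best <- min(dev)
  list(dev = best, states = unique(X[dev == best, , drop = FALSE]))
}

# exhaustive program search: every (tau, w) combination over every edge
o_fit <- function(net, subjects, tau_dom, w_dom, mode = "pred",
                  tie = "hold") {
  m <- nrow(net$edges)
  combos <- expand.grid(rep(list(seq_len(length(tau_dom) * length(w_dom))),
                            m))
  pairs <- expand.grid(tau = tau_dom, w = w_dom)
  ids <- net$nodes$id
  devs <- numeric(nrow(combos))
  keys <- character(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    taus <- pairs$tau[as.integer(combos[k, ])]
    ws <- pairs$w[as.integer(combos[k, ])]
    ed <- data.frame(source = net$edges$source, target = net$edges$target,
                     sign = net$edges$sign, tau = taus, weight = ws,
                     stringsAsFactors = FALSE)
    agg <- 0
    for (sub in subjects) {
      r <- o_impute(ids, sub$observed, ed, mode, tie)
      if (is.na(r$dev)) { agg <- Inf; break }
      agg <- agg + r$dev
    }
    devs[k] <- agg
    keys[k] <- paste(taus, ws, collapse = ";")
  }
  list(best = min(devs), keys = keys, devs = devs)
}

o_prog_key <- function(prog) {
  paste(prog$tau, prog$weight, collapse = ";")
}

# Benjamini-Hochberg step-up, written directly from the definition
o_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kstar <- 0
  for (k in seq_len(m)) if (ps[k] <= k / m * q) kstar <- k
  reject <- rep(FALSE, m)
  if (kstar > 0) reject[ord[1:kstar]] <- TRUE
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  list(adjusted = adjusted, reject = reject)
}

# nodes on at least one directed cycle, by depth-first path search
o_cycle_nodes <- function(edges, ids) {
  adj <- split(edges$target, edges$source)
  on_cycle <- character(0)
  for (start in ids) {
    stack <- list(start)
    visited <- character(0)
    found <- FALSE
    while (length(stack) && !found) {
      v <- stack[[1]]
      stack <- stack[-1]
      for (nb in adj[[v]]) {
        if (nb == start) { found <- TRUE; break }
        if (!nb %in% visited) {
          visited <- c(visited, nb)
          stack <- c(stack, nb)
        }
      }
    }
    if (found) on_cycle <- c(on_cycle, start)
  }
  on_cycle
}

# all-pairs shortest-path statistics by breadth-first search and path counts
o_path_stats <- function(edges, ids) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) adj[edges$source[r], edges$target[r]] <- TRUE
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  sigma <- matrix(0, n, n, dimnames = list(ids, ids))
  for (s in ids) {
    d[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in ids[adj[v, ]]) {
          if (is.infinite(d[s, u])) {
            d[s, u] <- d[s, v] + 1
            nxt <- c(nxt, u)
          }
          if (d[s, u] == d[s, v] + 1) {
            sigma[s, u] <- sigma[s, u] + sigma[s, v]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- setNames(numeric(n), ids)
  for (v in ids) {
    for (s in ids) {
      for (t in ids) {
        if (s == t || s == v || t == v) next
        if (is.finite(d[s, t]) && is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  list(d = d, betweenness = btw)
}
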