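#' Construct a signed regulatory network
#'
#' A `logic_network` holds a directed, signed regulatory graph over molecular,
#' behavioral and (at most one) exogenous stressor node, together with
#' per-edge literature-evidence counts. At most one edge is allowed per
#' ordered (source, target) pair; duplicate rows with the same sign are
#' collapsed, and rows with conflicting signs for the same pair are an error.
#'
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (+1/-1, or `"activate"`/`"inhibit"`), and optionally `n_citations`
#'   (nonnegative; 0 means unknown support).
#' @param nodes optional data.frame with columns `id`, `kind`
#'   (`"molecular"`, `"behavioral"` or `"stressor"`) and `polarity`
#'   (`"severity"`, `"function"` or `"none"`). Nodes referenced only by edges
#'   default to kind `"molecular"`, polarity `"none"`; behavioral and
#'   stressor nodes must be declared explicitly.
#' @param collapse how to combine `n_citations` across duplicate same-sign
#'   rows: `"sum"` (default; duplicates typically arise from merged exports)
#'   or `"max"`.
#' @param allow_self_loops permit edges with `source == target`?
#' @return an object of class `logic_network`: a list with data.frames
#'   `nodes` and `edges` (the latter gains a `low_confidence` flag, true iff
#'   `n_citations == 1`).
#' @export
logic_network <- function(edges, nodes = NULL, collapse = c("sum", "max"),
                          allow_self_loops = FALSE) {
  collapse <- match.arg(collapse)
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "sign") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- .parse_sign(edges$sign)
  if (is.null(edges$n_citations)) edges$n_citations <- 0L
  edges$n_citations <- as.integer(edges$n_citations)
  if (any(is.na(edges$n_citations)) || any(edges$n_citations < 0)) {
    stop("n_citations must be nonnegative integers (0 = unknown)")
  }

  key <- paste(edges$source, edges$target, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(edges$sign[key == k])) > 1L) {
      pr <- strsplit(k, "\r")[[1]]
      stop(sprintf("conflicting signs for edge (%s, %s)", pr[1], pr[2]))
    }
  }
  if (anyDuplicated(key)) {
    agg <- if (collapse == "sum") sum else max
    cit <- tapply(edges$n_citations, key, agg)
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$n_citations <- as.integer(cit[paste(edges$source, edges$target,
                                              sep = "\r")])
  }
  if (!allow_self_loops && any(edges$source == edges$target)) {
    stop("self-loop on node ", edges$source[edges$source == edges$target][1],
         " (enable allow_self_loops to permit)")
  }

  ids <- sort(unique(c(edges$source, edges$target)))
  if (is.null(nodes)) {
    nodes <- data.frame(id = ids, kind = "molecular", polarity = "none",
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
    nodes$id <- as.character(nodes$id)
    if (is.null(nodes$kind)) nodes$kind <- "molecular"
    if (is.null(nodes$polarity)) nodes$polarity <- "none"
    unknown <- setdiff(ids, nodes$id)
    if (length(unknown)) {
      stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
    }
  }
  rownames(nodes) <- rownames(edges) <- NULL
  edges$low_confidence <- edges$n_citations == 1L
  net <- structure(list(nodes = nodes, edges = edges), class = "logic_network")
  validate_network(net, allow_self_loops = allow_self_loops)
}

.parse_sign <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- tolower(as.character(x))
    out <- ifelse(x %in% c("activate", "activates", "+", "+1", "1"), 1L,
                  ifelse(x %in% c("inhibit", "inhibits", "-", "-1"), -1L,
                         NA_integer_))
  } else {
    out <- ifelse(x == 1, 1L, ifelse(x == -1, -1L, NA_integer_))
  }
  if (any(is.na(out))) stop("sign must be +1/-1 or activate/inhibit")
  as.integer(out)
}

#' Validate the structural invariants of a network
#'
#' Checks id uniqueness, node kinds and polarities, that every edge endpoint
#' exists, that there is at most one stressor node and that the stressor has
#' out-edges only. Cycle-closure (no pure sources or sinks among non-stressor
#' nodes) is a property of paper-shaped networks and is checked separately by
#' [validate_feedback_closure()].
#'
#' @param net a `logic_network`.
#' @param allow_self_loops permit self-loops?
#' @return `net`, invisibly usable, or an error.
#' @export
validate_network <- function(net, allow_self_loops = FALSE) {
  nodes <- net$nodes; edges <- net$edges
  if (any(!nzchar(nodes$id)) || anyDuplicated(nodes$id)) {
    stop("node ids must be nonempty and unique")
  }
  if (!all(nodes$kind %in% c("molecular", "behavioral", "stressor"))) {
    stop("node kind must be molecular, behavioral or stressor")
  }
  if (!all(nodes$polarity %in% c("severity", "function", "none"))) {
    stop("node polarity must be severity, function or none")
  }
  bad_pol <- nodes$polarity == "function" & nodes$kind != "behavioral"
  if (any(bad_pol)) {
    stop("polarity 'function' is only allowed for behavioral nodes: ",
         paste(nodes$id[bad_pol], collapse = ", "))
  }
  stressors <- nodes$id[nodes$kind == "stressor"]
  if (length(stressors) > 1L) stop("at most one stressor node is allowed")
  missing <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(missing)) {
    stop("edge references unknown node(s): ", paste(missing, collapse = ", "))
  }
  if (length(stressors) && any(edges$target == stressors)) {
    stop("stressor node '", stressors, "' may have out-edges only")
  }
  if (!allow_self_loops && any(edges$source == edges$target)) {
    stop("self-loops are not allowed")
  }
  net
}

#' @export
print.logic_network <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind,
                        c("molecular", "behavioral", "stressor")))
  cat(sprintf("<logic_network> %d nodes (%d molecular, %d behavioral, %d stressor), %d edges\n",
              nrow(x$nodes), kinds[1], kinds[2], kinds[3], nrow(x$edges)))
  invisible(x)
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("source", "target")],
                                directed = TRUE, vertices = net$nodes$id)
}

#' Check the feedback-closure invariant
#'
#' Paper-shaped networks admit no isolated source or terminal sink nodes:
#' every molecular and behavioral node must lie on at least one directed
#' cycle. The exogenous stressor is exempt (it is a pure input).
#'
#' @param net a `logic_network`.
#' @return character vector of non-stressor node ids that are not on any
#'   directed cycle; empty means compliant.
#' @export
validate_feedback_closure <- function(net) {
  g <- .as_igraph(net)
  comp <- igraph::components(g, mode = "strong")
  csize <- comp$csize[comp$membership]
  on_cycle <- csize > 1
  self <- net$nodes$id %in% net$edges$source[net$edges$source == net$edges$target]
  on_cycle <- on_cycle | self
  viol <- net$nodes$id[!on_cycle & net$nodes$kind != "stressor"]
  as.character(viol)
}

#' Summarize literature evidence behind the edges
#'
#' Computes the median citation count over edges with known support
#' (`n_citations > 0`) together with the counts of well-supported
#' (>= 5 citations) and single-citation (low-confidence) interactions.
#'
#' @param net a `logic_network`.
#' @return list of class `evidence_summary` with `median_citations`,
#'   `n_ge5`, `n_eq1`, `n_gt125` and `n_total`.
#' @export
summarize_evidence <- function(net) {
  cit <- net$edges$n_citations
  known <- cit[cit > 0]
  if (!length(known)) stop("no edges carry a known citation count")
  structure(list(median_citations = stats::median(known),
                 n_ge5 = sum(known >= 5),
                 n_eq1 = sum(known == 1),
                 n_gt125 = sum(known > 125),
                 n_total = nrow(net$edges)),
            class = "evidence_summary")
}

#' @export
print.evidence_summary <- function(x, ...) {
  cat(sprintf(paste0("<evidence_summary> %d edges; median %.1f citations; ",
                     "%d with >=5, %d with exactly 1, %d with >125\n"),
              x$n_total, x$median_citations, x$n_ge5, x$n_eq1, x$n_gt125))
  invisible(x)
}

#' Read a regulatory network from an edge list
#'
#' Accepts a delimited edge list (CSV or TSV by extension, with header
#' `source,target,sign[,n_citations]`) or a Cytoscape SIF file
#' (tab-delimited `source  activate|inhibit  target` lines). Node kinds and
#' polarities may be supplied through a node table with header
#' `id,kind,polarity`.
#'
#' @param path path to the edge list.
#' @param node_table optional path to a node table CSV, or a data.frame.
#' @param collapse,allow_self_loops passed to [logic_network()].
#' @return a `logic_network`.
#' @export
read_network <- function(path, node_table = NULL, collapse = c("sum", "max"),
                         allow_self_loops = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t")
    if (any(lengths(parts) != 3L)) {
      stop("SIF lines must be 'source<TAB>relation<TAB>target'")
    }
    edges <- data.frame(source = vapply(parts, `[`, "", 1L),
                        target = vapply(parts, `[`, "", 3L),
                        sign = vapply(parts, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  } else {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    edges <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
    if (!all(c("source", "target", "sign") %in% names(edges))) {
      stop("edge list must have columns source, target, sign")
    }
  }
  nodes <- node_table
  if (is.character(node_table)) {
    nodes <- utils::read.csv(node_table, stringsAsFactors = FALSE)
  }
  logic_network(edges, nodes, collapse = collapse,
                allow_self_loops = allow_self_loops)
}

#' Write a regulatory network
#'
#' `edge-csv` retains signs and citation counts and round-trips exactly
#' through [read_network()]; SIF keeps only the signed topology
#' (one `source activate|inhibit target` line per interaction).
#'
#' @param net a `logic_network`.
#' @param path output file path.
#' @param format `"edge-csv"` or `"sif"`.
#' @param node_table_path optional path for a companion node table CSV.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge-csv", "sif"),
                          node_table_path = NULL) {
  format <- match.arg(format)
  if (nrow(net$edges) == 0L) stop("refusing to write an empty network")
  if (format == "edge-csv") {
    out <- net$edges[, c("source", "target", "sign", "n_citations")]
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    rel <- ifelse(net$edges$sign > 0, "activate", "inhibit")
    writeLines(paste(net$edges$source, rel, net$edges$target, sep = "\t"),
               path)
  }
  if (!is.null(node_table_path)) {
    utils::write.csv(net$nodes[, c("id", "kind", "polarity")],
                     node_table_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
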