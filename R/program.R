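#' Construct a decisional-logic program
#'
#' A logic program assigns to every network edge a perception threshold
#' `tau` (the minimum source level at which the edge is perceived by its
#' target) and a positive integer weight (its influence magnitude), plus two
#' global rules: what a node does when its perceived input is balanced
#' (`tie_rule`: `"hold"` keeps the level, `"decay"` lets it relax one level
#' toward 0) and the update scheme (`"synchronous"` or `"asynchronous"`).
#'
#' @param net a `logic_network`.
#' @param tau integer vector of thresholds in 1..3, one per edge of `net`
#'   (recycled if length 1).
#' @param weight integer vector of positive weights, one per edge
#'   (recycled if length 1).
#' @param tie_rule `"hold"` or `"decay"`.
#' @param update_scheme `"synchronous"` or `"asynchronous"`.
#' @param w_max documented upper bound of the weight domain.
#' @return data.frame of class `logic_program` with columns `source`,
#'   `target`, `sign`, `tau`, `weight`, and attributes `tie_rule`,
#'   `update_scheme`, `w_max`.
#' @export
logic_program <- function(net, tau = 1L, weight = 1L, tie_rule = "hold",
                          update_scheme = c("synchronous", "asynchronous"),
                          w_max = max(2L, max(weight))) {
  update_scheme <- match.arg(update_scheme)
  m <- nrow(net$edges)
  tau <- as.integer(rep_len(tau, m))
  weight <- as.integer(rep_len(weight, m))
  if (any(tau < 1L | tau > 3L)) stop("tau must be in 1..3")
  if (any(weight < 1L)) stop("weights must be strictly positive")
  prog <- data.frame(source = net$edges$source, target = net$edges$target,
                     sign = net$edges$sign, tau = tau, weight = weight,
                     stringsAsFactors = FALSE)
  structure(prog, class = c("logic_program", "data.frame"),
            tie_rule = match.arg(tie_rule, c("hold", "decay")),
            update_scheme = update_scheme, w_max = as.integer(w_max))
}

#' @export
print.logic_program <- function(x, ...) {
  cat(sprintf("<logic_program> %d edges; tie_rule=%s, update=%s, w_max=%d\n",
              nrow(x), attr(x, "tie_rule"), attr(x, "update_scheme"),
              attr(x, "w_max")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Draw a random logic program
#'
#' Independent uniform draws of `tau` and `weight` per edge.
#'
#' @param net a `logic_network`.
#' @param tau_domain,w_domain nonempty integer domains.
#' @param tie_rule,update_scheme global rules, see [logic_program()].
#' @param seed optional integer seed for reproducibility.
#' @return a `logic_program`.
#' @export
sample_program <- function(net, tau_domain = 1:3, w_domain = 1:2,
                           tie_rule = "hold", update_scheme = "synchronous",
                           seed = NULL) {
  if (!length(tau_domain) || !length(w_domain)) stop("domains must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(net$edges)
  logic_program(net,
                tau = sample(as.integer(tau_domain), m, replace = TRUE),
                weight = sample(as.integer(w_domain), m, replace = TRUE),
                tie_rule = tie_rule, update_scheme = update_scheme,
                w_max = max(w_domain))
}

#' Serialize a logic program to JSON
#'
#' @param prog a `logic_program`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_program <- function(prog, path) {
  obj <- list(edges = as.data.frame(prog),
              tie_rule = attr(prog, "tie_rule"),
              update_scheme = attr(prog, "update_scheme"),
              w_max = attr(prog, "w_max"))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Read a logic program from JSON
#'
#' @param path JSON file written by [write_program()].
#' @param net the `logic_network` the program belongs to.
#' @return a `logic_program`.
#' @export
read_program <- function(path, net) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ed <- obj$edges
  al <- .align_program(net, data.frame(source = ed$source, target = ed$target,
                                       tau = ed$tau, weight = ed$weight,
                                       stringsAsFactors = FALSE))
  logic_program(net, tau = al$tau, weight = al$w, tie_rule = obj$tie_rule,
                update_scheme = obj$update_scheme, w_max = obj$w_max)
}
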