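#' Discretize an instrument score onto the 4-level qualitative scale
#'
#' Simple range normalization into four equal-width bins:
#' `level = min(3, floor(4 * (raw - scale_min) / (scale_max - scale_min)))`.
#'
#' @param raw numeric score(s) within the instrument scale.
#' @param scale_min,scale_max instrument scale range, `scale_max > scale_min`.
#' @return integer level(s) in 0..3.
#' @export
discretize_score <- function(raw, scale_min, scale_max) {
  if (scale_max <= scale_min) stop("scale_max must exceed scale_min")
  if (any(raw < scale_min | raw > scale_max)) {
    stop("raw score out of the instrument range [",
         scale_min, ", ", scale_max, "]")
  }
  as.integer(pmin(3, floor(4 * (raw - scale_min) / (scale_max - scale_min))))
}

#' Reverse a function-polarity scale
#'
#' Function scales (higher = better) are reversed at ingest so that inside
#' the engine every node is severity-like (higher = worse); e.g. low
#' executive function becomes high executive dysfunction. The map `3 - level`
#' is an involution.
#'
#' @param level integer level(s) in 0..3.
#' @return reversed level(s).
#' @export
reverse_function_scale <- function(level) {
  .check_levels(level)
  as.integer(3 - level)
}

#' Build a subject profile
#'
#' A partial observation of the network state: qualitative levels for the
#' behavioral constructs only.
#'
#' @param subject_id identifier.
#' @param observed named integer vector of levels 0..3, names are behavioral
#'   node ids.
#' @param net optional `logic_network` to validate the names against
#'   (observed keys must be behavioral nodes).
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, observed, net = NULL) {
  if (is.null(names(observed)) || any(!nzchar(names(observed)))) {
    stop("observed levels must be a named vector")
  }
  .check_levels(unname(observed))
  if (!is.null(net)) {
    beh <- net$nodes$id[net$nodes$kind == "behavioral"]
    bad <- setdiff(names(observed), beh)
    if (length(bad)) {
      stop("observed keys must be behavioral nodes; offending: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(subject_id = as.character(subject_id),
                 observed = setNames(as.integer(observed), names(observed))),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s: %s\n", x$subject_id,
              paste(names(x$observed), x$observed, sep = "=",
                    collapse = " ")))
  invisible(x)
}

#' The idealized control profile
#'
#' An artificial reference subject with minimal symptom severity and optimal
#' function: severity-polarity behavioral nodes at 0, function-polarity
#' nodes at 3. The control is required to sit at a stable resting state
#' (fixed point) in all fits.
#'
#' @param net a `logic_network`.
#' @return a `subject_profile` with `subject_id = "control"`.
#' @export
control_profile <- function(net) {
  beh <- net$nodes[net$nodes$kind == "behavioral", , drop = FALSE]
  if (!nrow(beh)) stop("network has no behavioral nodes")
  lev <- ifelse(beh$polarity == "function", 3L, 0L)
  subject_profile("control", setNames(as.integer(lev), beh$id), net)
}

#' Convert a profile to engine coordinates
#'
#' Applies [reverse_function_scale()] to function-polarity nodes so that all
#' levels are severity-like inside the engine. In engine coordinates the
#' idealized control is the all-zero behavioral profile.
#'
#' @param profile a `subject_profile` in instrument polarity.
#' @param net a `logic_network`.
#' @return a `subject_profile` in engine coordinates.
#' @export
as_engine_profile <- function(profile, net) {
  obs <- profile$observed
  pol <- net$nodes$polarity[match(names(obs), net$nodes$id)]
  if (anyNA(pol)) stop("profile references node(s) absent from the network: ",
                       paste(names(obs)[is.na(pol)], collapse = ", "))
  flip <- pol == "function"
  obs[flip] <- reverse_function_scale(obs[flip])
  subject_profile(profile$subject_id, obs)
}

#' Manhattan departure between a predicted state and an observation
#'
#' Sum of absolute level differences over the observed nodes, also expressed
#' as a fraction of the maximum possible misalignment (3 per compared node).
#'
#' @param predicted full state (named level vector) or any named vector
#'   covering the observed nodes.
#' @param observed a `subject_profile` or named level vector.
#' @return object of class `departure`: list with `absolute`, `normalized`,
#'   `n_compared`.
#' @export
manhattan_departure <- function(predicted, observed) {
  if (inherits(observed, "subject_profile")) observed <- observed$observed
  miss <- setdiff(names(observed), names(predicted))
  if (length(miss)) stop("predicted state is missing node(s): ",
                         paste(miss, collapse = ", "))
  d <- sum(abs(as.integer(predicted[names(observed)]) -
                 as.integer(observed)))
  n <- length(observed)
  structure(list(absolute = as.integer(d), normalized = d / (3 * n),
                 n_compared = n), class = "departure")
}

#' @export
print.departure <- function(x, ...) {
  cat(sprintf("<departure> absolute %d over %d nodes (%.1f%%)\n",
              x$absolute, x$n_compared, 100 * x$normalized))
  invisible(x)
}

#' Aggregate departures across subjects
#'
#' Total absolute departure over all subjects, normalized by
#' `3 * n_nodes * n_subjects` (e.g. 3 x 9 x 6 = 162 for the full study).
#'
#' @param per_subject nonempty list of `departure` objects computed over the
#'   same node set.
#' @return a `departure` with an extra `n_subjects` field.
#' @export
aggregate_departure <- function(per_subject) {
  if (!length(per_subject)) stop("need at least one departure")
  n_nodes <- unique(vapply(per_subject, function(d) as.integer(d$n_compared), 0L))
  if (length(n_nodes) != 1L) {
    stop("departures were computed over heterogeneous node sets")
  }
  abs_tot <- sum(vapply(per_subject, function(d) as.numeric(d$absolute), 0))
  k <- length(per_subject)
  structure(list(absolute = as.integer(abs_tot),
                 normalized = abs_tot / (3 * n_nodes * k),
                 n_compared = n_nodes, n_subjects = k),
            class = "departure")
}

#' Read an instrument-scale configuration
#'
#' YAML mapping each construct id to its instrument scale and polarity:
#' ```yaml
#' apathy:    {scale_min: 0, scale_max: 63, polarity: severity}
#' exec_fn:   {scale_min: 0, scale_max: 48, polarity: function}
#' ```
#'
#' @param path YAML file path.
#' @return data.frame with columns `construct`, `scale_min`, `scale_max`,
#'   `polarity`.
#' @export
read_scale_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read scale configurations")
  }
  cfg <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(names(cfg), function(nm) {
    entry <- cfg[[nm]]
    data.frame(construct = nm,
               scale_min = as.numeric(entry$scale_min),
               scale_max = as.numeric(entry$scale_max),
               polarity = entry$polarity %||% "severity",
               stringsAsFactors = FALSE)
  }))
  if (!all(out$polarity %in% c("severity", "function"))) {
    stop("polarity must be severity or function")
  }
  out
}

#' Discretize raw instrument totals into qualitative profiles
#'
#' Applies [discretize_score()] per construct according to a scale
#' configuration. The resulting profiles keep instrument polarity; apply
#' [as_engine_profile()] before fitting.
#'
#' @param raw data.frame with a `subject_id` column and one numeric column
#'   per construct named in `scales`.
#' @param scales data.frame from [read_scale_config()].
#' @return list of `subject_profile` objects.
#' @export
discretize_profiles <- function(raw, scales) {
  miss <- setdiff(scales$construct, names(raw))
  if (length(miss)) stop("raw scores missing construct(s): ",
                         paste(miss, collapse = ", "))
  lapply(seq_len(nrow(raw)), function(i) {
    lev <- vapply(seq_len(nrow(scales)), function(k) {
      discretize_score(raw[i, scales$construct[k]],
                       scales$scale_min[k], scales$scale_max[k])
    }, 0L)
    subject_profile(raw$subject_id[i], setNames(lev, scales$construct))
  })
}

#' Read subject profiles from CSV
#'
#' Expects one row per subject: a `subject_id` column followed by one
#' integer column (levels 0..3) per behavioral construct.
#'
#' @param path CSV path.
#' @param net optional network for validation.
#' @return list of `subject_profile` objects.
#' @export
read_profiles <- function(path, net = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df)) stop("profiles CSV needs a subject_id column")
  constructs <- setdiff(names(df), "subject_id")
  lapply(seq_len(nrow(df)), function(i) {
    subject_profile(df$subject_id[i],
                    setNames(as.integer(df[i, constructs]), constructs), net)
  })
}

#' Write subject profiles to CSV
#'
#' @param profiles list of `subject_profile` objects over a common node set.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  constructs <- names(profiles[[1]]$observed)
  rows <- lapply(profiles, function(p) {
    if (!setequal(names(p$observed), constructs)) {
      stop("profiles cover heterogeneous construct sets")
    }
    c(subject_id = p$subject_id, as.list(p$observed[constructs]))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
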