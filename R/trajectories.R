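# Longitudinal IR-trajectory classification and summaries.

#' Classify one ordered IR-profile sequence
#'
#' Classification is anchored on an optimal (`H-L`) baseline, mirroring the
#' longitudinal case studies that condition on pre-stress optimal IR:
#' subjects whose baseline is not `H-L` are labelled `not-classifiable`
#' (explicitly, never silently dropped). Otherwise a subject is a
#' `preserver` if every observed timepoint is `H-L`, a `reconstituter` if
#' some intermediate departs from `H-L` but the final timepoint regains it,
#' and a `degrader` if the final timepoint is not `H-L`. Missing intermediate
#' profiles are treated as unobserved; a missing final profile is an error.
#'
#' @param profiles character/factor sequence of IR profiles in time order
#'   (baseline first, final last); intermediate `NA`s allowed.
#' @return one of `"preserver"`, `"reconstituter"`, `"degrader"`,
#'   `"not-classifiable"`.
#' @export
classify_trajectory <- function(profiles) {
  profiles <- as.character(profiles)
  if (length(profiles) < 3L)
    stop("a trajectory needs at least 3 timepoints", call. = FALSE)
  baseline <- profiles[1L]
  final <- profiles[length(profiles)]
  if (is.na(baseline)) stop("baseline profile missing", call. = FALSE)
  if (is.na(final)) stop("final timepoint profile missing", call. = FALSE)
  if (baseline != "H-L") return("not-classifiable")
  observed <- profiles[!is.na(profiles)]
  if (all(observed == "H-L")) return("preserver")
  if (final == "H-L") return("reconstituter")
  "degrader"
}

#' Classify many subjects from a long-format table
#'
#' @param data data.frame with columns `subject`, `timepoint`, `profile`;
#'   timepoints must sort identically for every subject (factor level order
#'   or natural order).
#' @return data.frame with `subject`, `label`, `baseline`, `final`.
#' @export
classify_trajectories <- function(data) {
  need <- c("subject", "timepoint", "profile")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  tp <- if (is.factor(data$timepoint)) data$timepoint else
    factor(data$timepoint, levels = unique(data$timepoint[order(data$timepoint)]))
  split_idx <- split(seq_len(nrow(data)), data$subject)
  res <- lapply(split_idx, function(ix) {
    ord <- ix[order(tp[ix])]
    prof <- as.character(data$profile[ord])
    data.frame(label = classify_trajectory(prof),
               baseline = prof[1L], final = prof[length(prof)])
  })
  out <- do.call(rbind, res)
  data.frame(subject = names(split_idx), out, row.names = NULL)
}

#' Mean +/- SE readout trajectories per label group
#'
#' @param labels named character vector (or data.frame from
#'   [classify_trajectories()]) of per-subject trajectory labels.
#' @param readouts long data.frame with columns `subject`, `timepoint`,
#'   and one or more numeric readout columns.
#' @return long data.frame: `label`, `timepoint`, `readout`, `n`, `mean`,
#'   `se` (`se` is `NA` for groups with n < 2).
#' @export
trajectory_summary <- function(labels, readouts) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$subject)
  need <- c("subject", "timepoint")
  miss <- setdiff(need, names(readouts))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  vars <- setdiff(names(readouts), need)
  if (!length(vars)) stop("no readout columns supplied", call. = FALSE)
  lab <- labels[as.character(readouts$subject)]
  rows <- list()
  for (v in vars) {
    agg <- stats::aggregate(
      readouts[[v]],
      by = list(label = lab, timepoint = readouts$timepoint),
      FUN = function(x) c(n = sum(is.finite(x)),
                          mean = mean(x, na.rm = TRUE),
                          sd = stats::sd(x, na.rm = TRUE)))
    m <- agg$x
    rows[[v]] <- data.frame(label = agg$label, timepoint = agg$timepoint,
                            readout = v, n = m[, "n"], mean = m[, "mean"],
                            se = ifelse(m[, "n"] >= 2,
                                        m[, "sd"] / sqrt(m[, "n"]), NA_real_))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transition fractions between baseline and final states
#'
#' Row-stochastic contingency of state transitions; works for IHG grades and
#' IR profiles alike (e.g. the fraction of extreme IR-degraders that regain
#' IHG-I during convalescence).
#'
#' @param baseline_states,final_states equal-length factors/characters.
#' @return list with `counts` (contingency table) and `fractions`
#'   (row-stochastic matrix; rows with zero baseline count are `NaN`).
#' @export
transition_table <- function(baseline_states, final_states) {
  if (length(baseline_states) != length(final_states))
    stop("baseline and final state vectors differ in length", call. = FALSE)
  counts <- table(baseline = baseline_states, final = final_states)
  fractions <- prop.table(counts, margin = 1L)
  list(counts = counts, fractions = fractions)
}
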