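.ci95 <- function(x) {
  n <- sum(is.finite(x))
  if (n < 2L) return(NA_real_)
  1.96 * stats::sd(x, na.rm = TRUE) / sqrt(n)
}

#' Conditional accuracy function
#'
#' Accuracy as a function of binned reaction time, split by congruency.
#' Bins are half-open `[lo, hi)` (the last bin closed); empty bins are
#' kept with `n = 0` and `accuracy = NA`, never fabricated, and a
#' congruency class with no records is dropped with a warning.
#'
#' @param records Trial records with `rt_ms`, `correct` and `congruent`.
#' @param bin_edges Increasing RT bin edges; default: deciles of the
#'   pooled RT distribution.
#' @return A data frame (congruency x bin) with columns `congruent`,
#'   `bin`, `lo`, `hi`, `n`, `accuracy`.
#' @export
conditional_accuracy <- function(records, bin_edges = NULL) {
  stopifnot(nrow(records) > 0)
  records <- records[!is.na(records$congruent), , drop = FALSE]
  if (nrow(records) == 0L) stop("no records with congruency information")
  if (is.null(bin_edges))
    bin_edges <- unique(stats::quantile(records$rt_ms, probs = seq(0, 1, 0.1),
                                        names = FALSE))
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("`bin_edges` must be strictly increasing")
  nb <- length(bin_edges) - 1L
  out <- list()
  for (con in c(TRUE, FALSE)) {
    sub <- records[records$congruent == con, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no ", if (con) "congruent" else "incongruent",
              " records; class dropped")
      next
    }
    bin <- findInterval(sub$rt_ms, bin_edges, rightmost.closed = TRUE)
    bin[bin < 1L | bin > nb] <- NA
    acc <- vapply(seq_len(nb), function(b) {
      idx <- which(bin == b)
      if (!length(idx)) NA_real_ else mean(sub$correct[idx])
    }, numeric(1))
    n <- vapply(seq_len(nb), function(b) sum(bin == b, na.rm = TRUE),
                numeric(1))
    out[[length(out) + 1L]] <-
      data.frame(congruent = con, bin = seq_len(nb),
                 lo = bin_edges[-(nb + 1L)], hi = bin_edges[-1L],
                 n = as.integer(n), accuracy = acc)
  }
  do.call(rbind, out)
}

#' Gratton sequential-congruency summary
#'
#' Mean reaction times in the four (previous x current) congruency cells
#' -- cC, iC, cI, iI -- and the sequential interaction
#' `(cI - cC) - (iI - iC)`. Records without a previous-trial tag (each
#' agent's first trial) are excluded.
#'
#' @param records Flanker-style trial records.
#' @return A list with `cells` (data frame: `prev`, `current`,
#'   `mean_rt`, `ci95`, `n`), the `interaction`, per-agent interactions
#'   (`by_agent`), and the across-agent 95% half-width
#'   `interaction_ci95`.
#' @export
gratton_summary <- function(records) {
  r <- records[!is.na(records$prev_congruent) & !is.na(records$congruent), ,
               drop = FALSE]
  cell_label <- function(prev, cur)
    paste0(ifelse(prev, "c", "i"), ifelse(cur, "C", "I"))
  lab <- cell_label(r$prev_congruent, r$congruent)
  cells <- expand.grid(prev = c(TRUE, FALSE), current = c(TRUE, FALSE))
  cells$label <- cell_label(cells$prev, cells$current)
  cells$mean_rt <- vapply(cells$label, function(l)
    mean(r$rt_ms[lab == l]), numeric(1))
  cells$ci95 <- vapply(cells$label, function(l)
    .ci95(r$rt_ms[lab == l]), numeric(1))
  cells$n <- vapply(cells$label, function(l) sum(lab == l), integer(1))
  inter_one <- function(sub, sublab) {
    m <- vapply(c("cC", "cI", "iC", "iI"), function(l)
      mean(sub$rt_ms[sublab == l]), numeric(1))
    (m["cI"] - m["cC"]) - (m["iI"] - m["iC"])
  }
  by_agent <- vapply(split(seq_len(nrow(r)), r$agent), function(idx)
    inter_one(r[idx, , drop = FALSE], lab[idx]), numeric(1))
  list(cells = cells,
       interaction = unname(inter_one(r, lab)),
       by_agent = by_agent,
       interaction_ci95 = .ci95(by_agent))
}

#' Grid-world learning curves
#'
#' Across-agent means, per miniblock, of the first-trial reaction time
#' (as number of samples) and of the miniblock success fraction.
#'
#' @param records Grid-world trial records.
#' @return A data frame per miniblock: `miniblock`, `mean_n_samples`,
#'   `rt_ci95`, `accuracy`, `acc_ci95`, `n_agents`.
#' @export
learning_curves <- function(records) {
  first <- records[records$trial == 1L, , drop = FALSE]
  mbs <- sort(unique(first$miniblock))
  out <- lapply(mbs, function(mb) {
    sub <- first[first$miniblock == mb, , drop = FALSE]
    data.frame(miniblock = mb,
               mean_n_samples = mean(sub$n_samples),
               rt_ci95 = .ci95(sub$n_samples),
               accuracy = mean(sub$correct),
               acc_ci95 = .ci95(as.numeric(sub$correct)),
               n_agents = nrow(sub))
  })
  do.call(rbind, out)
}

#' Mean success over a post-switch window
#'
#' The headline grid-world quantity: the fraction of successful
#' miniblocks over a window of miniblocks, averaged across agents.
#'
#' @param records Grid-world trial records.
#' @param window Miniblock indices (default 101:105, the five miniblocks
#'   after the goal switch).
#' @return The mean success proportion.
#' @export
post_switch_success <- function(records, window = 101:105) {
  first <- records[records$trial == 1L & records$miniblock %in% window, ,
                   drop = FALSE]
  if (nrow(first) == 0L) stop("no records in the requested window")
  mean(first$correct)
}

#' Task-switching cell summary
#'
#' Mean reaction times by trials-since-switch, congruency and training
#' length, with across-agent 95% half-widths.
#'
#' @param records Task-switching trial records (switching phase rows).
#' @return A data frame of cell means.
#' @export
switching_summary <- function(records) {
  r <- records[!is.na(records$trials_since_switch), , drop = FALSE]
  cells <- unique(r[, c("trials_since_switch", "congruent",
                        "training_length")])
  cells <- cells[order(cells$training_length, cells$trials_since_switch,
                       cells$congruent), , drop = FALSE]
  summ <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- r[r$trials_since_switch == cells$trials_since_switch[i] &
               r$congruent == cells$congruent[i] &
               r$training_length == cells$training_length[i], ,
             drop = FALSE]
    agent_means <- tapply(sub$rt_ms, sub$agent, mean)
    data.frame(cells[i, , drop = FALSE],
               mean_rt = mean(sub$rt_ms),
               ci95 = .ci95(as.numeric(agent_means)),
               accuracy = mean(sub$correct),
               n = nrow(sub), row.names = NULL)
  })
  do.call(rbind, summ)
}

#' Summary of a swept parameter
#'
#' Mean reaction time (95% across-agent half-width) per value of a swept
#' parameter column, e.g. `epsilon` or `gamma`.
#'
#' @param records Stacked sweep records (see [run_taskswitch_sweep()]).
#' @param parameter Name of the swept column.
#' @param switch_only If `TRUE`, only switch trials
#'   (`trials_since_switch == 1`) enter the summary.
#' @return A data frame: parameter value, `mean_rt`, `ci95`, `accuracy`,
#'   `n`.
#' @export
sweep_summary <- function(records, parameter, switch_only = FALSE) {
  stopifnot(parameter %in% names(records))
  r <- records[!is.na(records$trials_since_switch), , drop = FALSE]
  if (switch_only)
    r <- r[r$trials_since_switch == 1L, , drop = FALSE]
  vals <- sort(unique(r[[parameter]]))
  out <- lapply(vals, function(v) {
    sub <- r[r[[parameter]] == v, , drop = FALSE]
    agent_means <- tapply(sub$rt_ms, sub$agent, mean)
    df <- data.frame(value = v, mean_rt = mean(sub$rt_ms),
                     ci95 = .ci95(as.numeric(agent_means)),
                     accuracy = mean(sub$correct), n = nrow(sub))
    names(df)[1L] <- parameter
    df
  })
  do.call(rbind, out)
}

#' Reaction-time distribution shape
#'
#' Sample skewness of the raw and log-transformed reaction times and an
#' Anderson-Darling normality statistic of the log reaction times.
#' Simulated reaction times are characteristically right-skewed on the
#' raw scale and near-symmetric after the log transform.
#'
#' @param rts At least 20 positive, non-constant reaction times.
#' @return A list: `skew_raw`, `skew_log`, `log_normality_stat`,
#'   `log_normality_p` (Anderson-Darling on `log(rts)`).
#' @export
rt_distribution_stats <- function(rts) {
  if (length(rts) < 20L) stop("need at least 20 reaction times")
  if (any(rts <= 0)) stop("reaction times must be positive")
  if (stats::sd(rts) == 0) stop("degenerate (constant) sample")
  ad <- nortest::ad.test(log(rts))
  list(skew_raw = e1071::skewness(rts),
       skew_log = e1071::skewness(log(rts)),
       log_normality_stat = unname(ad$statistic),
       log_normality_p = ad$p.value)
}
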