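# Cascade classification of per-trace step lists into vesicle fates.
# Analysis rule: only spots with exactly one stepwise increase during the
# association period are analyzed; at most one fusion event per associated
# SV-PM pair.

#' Classify one trace's step events into a vesicle record
#'
#' Applies the cascade rule: exactly one step during the association period
#' marks an associated SV-PM vesicle pair (zero steps or two or more steps
#' exclude the trace); a subsequent step during the spontaneous period marks
#' spontaneous fusion; otherwise a step during the triggered period at or
#' after the Ca2+ arrival time marks Ca2+-triggered fusion, with latency
#' measured from `t_Ca`. A triggered-period step before `t_Ca` excludes the
#' trace, since spontaneous statistics are defined over the spontaneous
#' period only. At most one fusion event is recorded per pair; any steps
#' after the fusion event are counted as anomalies in `n_extra_steps`.
#'
#' @param steps Data frame of step events (`t_step`, `amplitude`, `score`),
#'   sorted by time — as returned by [detect_steps()].
#' @param schedule An [acquisition_schedule()].
#' @param t_Ca Ca2+ arrival time, seconds; must lie within the triggered
#'   period.
#' @param spot_id Identifier copied into the record.
#' @return One-row data frame with columns `spot_id`, `assoc_time`, `fate`
#'   (one of `"excluded"`, `"no_fusion"`, `"spontaneous"`, `"triggered"`),
#'   `fusion_time`, `latency`, `exclusion_reason`, `n_extra_steps`.
#' @examples
#' sched <- acquisition_schedule()
#' st <- data.frame(t_step = c(20, 131.5), amplitude = c(300, 320),
#'                  score = c(15, 16))
#' classify_trace(st, sched, t_Ca = 130.2)   # triggered, latency 1.3 s
#' @export
classify_trace <- function(steps, schedule, t_Ca, spot_id = NA_integer_) {
  validate_schedule(schedule)
  if (t_Ca < schedule$trig_start || t_Ca >= schedule$trig_end)
    stop("t_Ca outside the triggered period")
  if (nrow(steps) > 0 && is.unsorted(steps$t_step))
    stop("steps must be sorted by t_step")

  rec <- function(fate, assoc_time = NA_real_, fusion_time = NA_real_,
                  latency = NA_real_, reason = NA_character_, extra = 0L) {
    data.frame(spot_id = spot_id, assoc_time = assoc_time, fate = fate,
               fusion_time = fusion_time, latency = latency,
               exclusion_reason = reason, n_extra_steps = extra,
               stringsAsFactors = FALSE)
  }

  per <- period_of(steps$t_step, schedule)
  s1 <- steps$t_step[!is.na(per) & per == "assoc"]
  s2 <- steps$t_step[!is.na(per) & per == "spont"]
  s3 <- steps$t_step[!is.na(per) & per == "trig"]

  if (length(s1) == 0L)
    return(rec("excluded", reason = "no association"))
  if (length(s1) >= 2L)
    return(rec("excluded", reason = "multiple association-period steps"))

  assoc_time <- s1[1L]
  if (length(s2) > 0L) {
    # first spontaneous-period step is the fusion; later steps are anomalies
    return(rec("spontaneous", assoc_time, fusion_time = s2[1L],
               extra = length(s2) - 1L + length(s3)))
  }
  if (length(s3) > 0L) {
    if (s3[1L] < t_Ca)
      return(rec("excluded", assoc_time,
                 reason = "pre-injection step in triggered period"))
    return(rec("triggered", assoc_time, fusion_time = s3[1L],
               latency = s3[1L] - t_Ca, extra = length(s3) - 1L))
  }
  rec("no_fusion", assoc_time)
}

#' Build a condition-level event table from vesicle records
#'
#' Collects the classified records of one acquisition round under a
#' condition label and tallies associated, spontaneous and triggered
#' vesicles. Excluded records are retained with their reasons so the
#' exclusion step is auditable.
#'
#' @param records Data frame of rows from [classify_trace()].
#' @param condition Condition label (e.g. `"Cpx 2 uM"`, `"no Cpx"`).
#' @param round_id Acquisition-round identifier.
#' @param t_Ca Ca2+ arrival time of this round, seconds.
#' @param schedule The [acquisition_schedule()] the records refer to.
#' @return An object of class `"sv_event_table"`: a list with `condition`,
#'   `records` (with a `round_id` column added), `t_Ca` (named by round),
#'   `schedule`, and counts `n_associated`, `n_spontaneous`, `n_triggered`,
#'   `n_excluded`.
#' @export
build_event_table <- function(records, condition, round_id = "r1", t_Ca,
                              schedule) {
  validate_schedule(schedule)
  if (nrow(records) > 0 && anyDuplicated(records$spot_id))
    stop("duplicate spot_id in records")
  records$round_id <- if (nrow(records) > 0) as.character(round_id) else character(0)
  tca <- stats::setNames(t_Ca, as.character(round_id))
  tab <- structure(list(condition = condition, records = records,
                        t_Ca = tca, schedule = schedule),
                   class = "sv_event_table")
  tab[c("n_associated", "n_spontaneous", "n_triggered", "n_excluded")] <-
    event_counts(tab)
  tab
}

event_counts <- function(tab) {
  f <- tab$records$fate
  list(n_associated = sum(f %in% c("no_fusion", "spontaneous", "triggered")),
       n_spontaneous = sum(f == "spontaneous"),
       n_triggered = sum(f == "triggered"),
       n_excluded = sum(f == "excluded"))
}

#' @export
print.sv_event_table <- function(x, ...) {
  cat(sprintf("Event table: condition '%s', %d round(s)\n",
              x$condition, length(x$t_Ca)))
  cat(sprintf("  traces %d | associated %d | spontaneous %d | triggered %d | excluded %d\n",
              nrow(x$records), x$n_associated, x$n_spontaneous,
              x$n_triggered, x$n_excluded))
  invisible(x)
}

#' Merge event tables from repeat acquisition rounds
#'
#' The acquisition procedure is repeated in different imaging areas of the
#' same flow chamber (five rounds in a typical experiment); this merges the
#' per-round tables of one condition, preserving per-round provenance for
#' replicate statistics. Spot ids are namespaced by round, so the same
#' numeric id may recur across rounds.
#'
#' @param tables List of `"sv_event_table"` objects sharing one condition.
#' @return A merged `"sv_event_table"` with summed counts.
#' @export
merge_rounds <- function(tables) {
  if (length(tables) == 0L) stop("no tables to merge")
  if (length(tables) == 1L) return(tables[[1L]])
  conds <- unique(vapply(tables, `[[`, character(1), "condition"))
  if (length(conds) != 1L)
    stop("cannot merge tables with mixed conditions: ",
         paste(conds, collapse = ", "))
  recs <- do.call(rbind, lapply(tables, `[[`, "records"))
  uid <- paste(recs$round_id, recs$spot_id, sep = ":")
  if (anyDuplicated(uid)) stop("duplicate spot_id within a round")
  tca <- do.call(c, lapply(tables, `[[`, "t_Ca"))
  if (anyDuplicated(names(tca))) stop("duplicate round_id across tables")
  tab <- structure(list(condition = conds, records = recs, t_Ca = tca,
                        schedule = tables[[1L]]$schedule),
                   class = "sv_event_table")
  tab[c("n_associated", "n_spontaneous", "n_triggered", "n_excluded")] <-
    event_counts(tab)
  tab
}

#' Per-round summary counts and rates
#'
#' One row per acquisition round with associated / spontaneous / triggered
#' tallies and the per-round spontaneous events per associated vesicle —
#' the replicate-level quantities used for condition comparisons.
#'
#' @param table An `"sv_event_table"`.
#' @return Data frame with columns `round_id`, `n_associated`,
#'   `n_spontaneous`, `n_triggered`, `spont_per_vesicle`.
#' @export
per_round_counts <- function(table) {
  rounds <- names(table$t_Ca)
  out <- do.call(rbind, lapply(rounds, function(r) {
    f <- table$records$fate[table$records$round_id == r]
    na <- sum(f %in% c("no_fusion", "spontaneous", "triggered"))
    data.frame(round_id = r, n_associated = na,
               n_spontaneous = sum(f == "spontaneous"),
               n_triggered = sum(f == "triggered"),
               spont_per_vesicle = if (na > 0) sum(f == "spontaneous") / na
                                   else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
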