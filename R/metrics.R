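#' First threshold crossing per item
#'
#' Reduces a crossing log (columns `time`, `item`, and optionally `act`)
#' to the first upward crossing of each item, ordered in time. Crossings
#' recorded at the same integration step are ordered by descending
#' activation at that step (a deterministic tie-break; exact ties are
#' measure-zero but Euler steps can collide).
#'
#' @param crossings Data frame with columns `time`, `item` and optionally
#'   `act`.
#' @return Data frame of one row per item, in recall order.
#' @export
first_crossings <- function(crossings) {
  if (!nrow(crossings)) return(crossings)
  act <- if ("act" %in% names(crossings)) crossings$act else numeric(nrow(crossings))
  ord <- order(crossings$time, -act)
  crossings <- crossings[ord, , drop = FALSE]
  crossings <- crossings[!duplicated(crossings$item), , drop = FALSE]
  rownames(crossings) <- NULL
  crossings
}

#' Recall accuracy
#'
#' Percent of target items recalled in the correct order: credit accrues
#' along the crossing order for as long as it matches the target prefix;
#' the first out-of-order crossing — including any crossing by an item
#' outside the target — ends credit for it and all further items. For a
#' five-item target the possible values are 0, 20, 40, 60, 80, 100.
#'
#' @param crossing_order Character vector of items in the order of their
#'   first threshold crossings (see [first_crossings()]), or a crossing
#'   data frame.
#' @param target Character vector: the sequence being tested.
#' @return Accuracy in percent.
#' @export
#' @examples
#' recall_accuracy(c("A", "B", "D", "C", "E"), c("A", "B", "C", "D", "E"))  # 40
recall_accuracy <- function(crossing_order, target) {
  if (is.data.frame(crossing_order))
    crossing_order <- first_crossings(crossing_order)$item
  if (!length(target)) stop("target sequence must be non-empty")
  k <- 0L
  for (lab in crossing_order) {
    if (k < length(target) && identical(lab, target[k + 1L])) k <- k + 1L
    else break
  }
  100 * k / length(target)
}

#' Recall time
#'
#' For a fully accurate recall, the interval from cue onset to the first
#' threshold crossing of the final target item, provided it occurs before
#' the ceiling; any recall with accuracy below 100% — or completing at or
#' beyond the ceiling — is assigned the ceiling value (30 s by default).
#'
#' @param crossings Crossing data frame (`time` relative to cue onset,
#'   `item`).
#' @param target Character vector: the sequence being tested.
#' @param accuracy Accuracy in percent from [recall_accuracy()].
#' @param cue_onset Time of cue onset on the crossing clock (default 0).
#' @param params A [model_params()] (supplies the ceiling).
#' @return Recall time in seconds.
#' @export
recall_time <- function(crossings, target, accuracy, cue_onset = 0,
                        params = model_params()) {
  ceiling_s <- params$recall_ceiling
  if (accuracy < 100) return(ceiling_s)
  fc <- first_crossings(crossings)
  t_final <- fc$time[match(target[length(target)], fc$item)] - cue_onset
  if (is.na(t_final) || t_final >= ceiling_s) ceiling_s else t_final
}

#' Assemble a recall result
#'
#' @param crossings Crossing data frame (times relative to cue onset).
#' @param cue Cue item label.
#' @param target Character vector: the target sequence.
#' @param params A [model_params()].
#' @return An object of class `recall_result` with the deduplicated
#'   crossing order, `accuracy` (percent) and `recall_time` (seconds).
#' @export
make_recall_result <- function(crossings, cue, target, params = model_params()) {
  fc <- first_crossings(crossings)
  acc <- recall_accuracy(fc$item, target)
  rt <- recall_time(fc, target, acc, cue_onset = 0, params = params)
  structure(list(cue = cue, target = target, crossings = fc,
                 accuracy = acc, recall_time = rt),
            class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("<recall_result> cue %s -> target %s\n", x$cue,
              paste(x$target, collapse = "")))
  cat(sprintf("  crossings: %s\n",
              if (nrow(x$crossings)) paste(x$crossings$item, collapse = " ") else "(none)"))
  cat(sprintf("  accuracy: %g%%; recall time: %g s\n", x$accuracy, x$recall_time))
  invisible(x)
}

#' Replay statistics over a set of sleep records
#'
#' Per night: the histogram of cue items, each sequence's share of the
#' non-null cued UP states (in percent; cues owned by no sequence, or by
#' more than one, count as unattributed), and the mean duration of full
#' replays per sequence. Nights with no non-null cue have no share rows.
#'
#' @param records Data frame of replay records as produced by
#'   [run_sleep_block()] (columns `night`, `up`, `cue`, `full_replay`,
#'   `duration`).
#' @param sequences Named list of item vectors.
#' @return A list with data frames `shares` (night, sequence, n_cued,
#'   share_pct), `histogram` (night, item, count) and `durations` (night,
#'   sequence, n_full, mean_duration).
#' @export
replay_statistics <- function(records, sequences) {
  records$attributed <- vapply(records$cue, attribute_cue, character(1),
                               sequences = sequences)
  non_null <- records[!is.na(records$cue), , drop = FALSE]
  orphans <- unique(non_null$cue[is.na(non_null$attributed)])
  if (length(orphans))
    warning("cue item(s) not attributable to a unique sequence: ",
            paste(orphans, collapse = ", "))

  nights <- sort(unique(records$night))
  labels <- c(names(sequences), "unattributed")
  shares <- list(); durations <- list(); hist <- list()
  for (nt in nights) {
    rn <- non_null[non_null$night == nt, , drop = FALSE]
    if (nrow(rn)) {
      attr_lab <- ifelse(is.na(rn$attributed), "unattributed", rn$attributed)
      counts <- vapply(labels, function(l) sum(attr_lab == l), numeric(1))
      shares[[length(shares) + 1L]] <- data.frame(
        night = nt, sequence = labels, n_cued = as.integer(counts),
        share_pct = 100 * counts / nrow(rn), stringsAsFactors = FALSE)
      tab <- table(rn$cue)
      hist[[length(hist) + 1L]] <- data.frame(
        night = nt, item = names(tab), count = as.integer(tab),
        stringsAsFactors = FALSE)
      full <- rn[rn$full_replay, , drop = FALSE]
      if (nrow(full)) {
        for (sq in unique(full$attributed[!is.na(full$attributed)])) {
          d <- full$duration[full$attributed == sq & !is.na(full$attributed)]
          durations[[length(durations) + 1L]] <- data.frame(
            night = nt, sequence = sq, n_full = length(d),
            mean_duration = mean(d), stringsAsFactors = FALSE)
        }
      }
    }
  }
  bind0 <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  list(shares = bind0(shares, data.frame(night = integer(), sequence = character(),
                                         n_cued = integer(), share_pct = numeric())),
       histogram = bind0(hist, data.frame(night = integer(), item = character(),
                                          count = integer())),
       durations = bind0(durations, data.frame(night = integer(), sequence = character(),
                                               n_full = integer(), mean_duration = numeric())))
}
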