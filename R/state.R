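#' Plasticity gates
#'
#' Booleans enabling the Hebbian/depression part of the learning rule per
#' region and behavioural mode. Passive weight decay is never gated: a
#' disabled gate leaves weights decaying toward zero. By default learning
#' is enabled everywhere, including slow-wave sleep.
#'
#' @param hc_learning_wake,hc_learning_sleep,ctx_learning_wake,ctx_learning_sleep
#'   Logical flags.
#' @return An object of class `plasticity_gates`.
#' @export
plasticity_gates <- function(hc_learning_wake = TRUE, hc_learning_sleep = TRUE,
                             ctx_learning_wake = TRUE, ctx_learning_sleep = TRUE) {
  g <- list(hc_learning_wake = isTRUE(hc_learning_wake),
            hc_learning_sleep = isTRUE(hc_learning_sleep),
            ctx_learning_wake = isTRUE(ctx_learning_wake),
            ctx_learning_sleep = isTRUE(ctx_learning_sleep))
  class(g) <- "plasticity_gates"
  g
}

#' Region state
#'
#' State of one memory region (hippocampus or cortex): item activations
#' `a`, inactivation currents `g` (both in \[0, 1\]), the adaptive weight
#' matrix `W` (row = presynaptic item, entries in \[0, 1\]) and the
#' link-existence mask `exists`. Weights are identically zero wherever no
#' link has been instantiated; there are no self-links.
#'
#' @param n_items Number of items.
#' @param tag `"HC"` or `"CTX"`.
#' @param learning_enabled Logical; region-level learning switch.
#' @return An object of class `region_state`.
#' @export
region_state <- function(n_items, tag = c("CTX", "HC"), learning_enabled = TRUE) {
  tag <- match.arg(tag)
  n_items <- as.integer(n_items)
  stopifnot(n_items >= 0)
  r <- list(tag = tag,
            a = numeric(n_items),
            g = numeric(n_items),
            W = matrix(0, n_items, n_items),
            exists = matrix(FALSE, n_items, n_items),
            learning_enabled = isTRUE(learning_enabled))
  class(r) <- "region_state"
  r
}

#' Network state
#'
#' Full simulation state: both regions, the salience vector, the simulated
#' clock, the behavioural mode (wake or sleep) and the lesion flag for the
#' hippocampus-to-cortex feedback. The item catalog maps percept labels to
#' neuron indices shared by both regions (items are linked one-to-one
#' across regions) and only ever grows.
#'
#' @param items Character vector of initial percept labels (may be empty;
#'   items can be allocated later with [add_items()]).
#' @param params A [model_params()] object (used only for validation here;
#'   operations take parameters explicitly).
#' @param gates A [plasticity_gates()] object.
#' @param hc_to_ctx_enabled Logical; `FALSE` lesions the feedback
#'   projections from hippocampus to cortex.
#' @return An object of class `network_state`.
#' @export
#' @examples
#' st <- network_state(c("A", "B", "C"))
#' st$catalog
network_state <- function(items = character(), params = model_params(),
                          gates = plasticity_gates(),
                          hc_to_ctx_enabled = TRUE) {
  items <- as.character(items)
  if (anyDuplicated(items)) stop("item labels must be unique")
  n <- length(items)
  st <- list(catalog = items,
             ctx = region_state(n, "CTX"),
             hc = region_state(n, "HC"),
             salience = setNames(numeric(n), items),
             clock = 0,
             mode = "wake",
             hc_to_ctx_enabled = isTRUE(hc_to_ctx_enabled),
             gates = gates)
  class(st) <- "network_state"
  st
}

#' Allocate new items in the catalog
#'
#' Grows both regions (and the salience vector) by the given novel labels,
#' as when an unfamiliar percept is first presented and a matching item
#' has to be allocated. Labels already present are ignored.
#'
#' @param state A [network_state()].
#' @param labels Character vector of percept labels.
#' @return The updated state.
#' @export
add_items <- function(state, labels) {
  labels <- as.character(labels)
  new <- setdiff(labels, state$catalog)
  if (!length(new)) return(state)
  k <- length(new)
  grow_region <- function(r) {
    n0 <- length(r$a)
    n1 <- n0 + k
    W <- matrix(0, n1, n1); W[seq_len(n0), seq_len(n0)] <- r$W
    ex <- matrix(FALSE, n1, n1); ex[seq_len(n0), seq_len(n0)] <- r$exists
    r$a <- c(r$a, numeric(k))
    r$g <- c(r$g, numeric(k))
    r$W <- W
    r$exists <- ex
    r
  }
  state$ctx <- grow_region(state$ctx)
  state$hc <- grow_region(state$hc)
  state$salience <- c(state$salience, setNames(numeric(k), new))
  state$catalog <- c(state$catalog, new)
  state
}

#' Reset transient state
#'
#' Zeroes all item activations and inactivation currents in both regions,
#' leaving weights, link masks and salience untouched. Applied at the end
#' of every UP state (the start of the next DOWN state) and at the start
#' of each experiment.
#'
#' @param state A [network_state()].
#' @return The updated state.
#' @export
reset_transients <- function(state) {
  state$ctx$a[] <- 0
  state$ctx$g[] <- 0
  state$hc$a[] <- 0
  state$hc$g[] <- 0
  state
}

item_index <- function(state, labels) {
  idx <- match(labels, state$catalog)
  if (anyNA(idx))
    stop("unknown item label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  idx
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state>\n")
  cat("  items:", if (length(x$catalog)) paste(x$catalog, collapse = " ") else "(none)", "\n")
  cat(sprintf("  clock: %.3f s; mode: %s; HC->CTX feedback: %s\n",
              x$clock, x$mode,
              if (x$hc_to_ctx_enabled) "intact" else "lesioned"))
  cat(sprintf("  links: %d (CTX), %d (HC)\n",
              sum(x$ctx$exists), sum(x$hc$exists)))
  invisible(x)
}
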