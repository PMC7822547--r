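#' Health states of the DFU model
#'
#' The model distinguishes five health states: an open uninfected ulcer, a
#' closed (healed) ulcer, an infected ulcer, post-amputation, and death.
#' Death is absorbing; amputation can only be left through death.
#'
#' @return Character vector of the five state labels, in the internal coding
#'   order (integer codes 1 to 5 elsewhere in the package).
#' @export
dfu_states <- function() {
  c("uninfected", "closed", "infected", "amputation", "dead")
}

# integer codes used by the engine
.S_UNINF <- 1L
.S_CLOSED <- 2L
.S_INFECTED <- 3L
.S_AMP <- 4L
.S_DEAD <- 5L

.state_index <- function(label) {
  i <- match(label, dfu_states())
  if (anyNA(i)) stop("unknown health state: ", paste(label[is.na(i)], collapse = ", "))
  i
}
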