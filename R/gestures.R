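#' Gesture vocabulary of the armband protocol
#'
#' The armband discriminates eight hand postures. Codes 0--7 follow the
#' acquisition protocol ordering (rest first, clenched fist last) and are the
#' byte values emitted by the streaming decoder.
#'
#' @return Character vector of the eight gesture names, in protocol order
#'   (code = position - 1).
#' @export
#' @examples
#' gesture_labels()
#' gesture_code("clenched_fist")  # 7
gesture_labels <- function() {
  c("rest", "wrist_flexion", "wrist_extension", "wrist_adduction",
    "wrist_abduction", "wrist_rotation", "fingers_abduction", "clenched_fist")
}

#' Integer code of a gesture label
#'
#' @param label character vector of gesture names.
#' @return Integer vector of codes in 0--7.
#' @export
gesture_code <- function(label) {
  idx <- match(label, gesture_labels())
  if (anyNA(idx)) {
    stop("unknown gesture label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  as.integer(idx - 1L)
}

#' Gesture label of an integer code
#'
#' @param code integer vector of codes in 0--7.
#' @return Character vector of gesture names.
#' @export
gesture_from_code <- function(code) {
  code <- as.integer(code)
  if (any(code < 0L | code > 7L)) stop("gesture codes must lie in 0..7")
  gesture_labels()[code + 1L]
}

#' Sensor channels and their target muscles
#'
#' Channel 1 sits on flexor carpi ulnaris, channel 2 on flexor carpi
#' radialis, channel 3 on extensor digitorum; these muscles drive,
#' respectively, wrist flexion/adduction, wrist flexion/abduction, and
#' finger extension/abduction plus wrist extension.
#'
#' @return A data.frame with columns `index` (1--3) and `muscle`.
#' @export
sensor_channels <- function() {
  data.frame(
    index = 1:3,
    muscle = c("flexor_carpi_ulnaris", "flexor_carpi_radialis",
               "extensor_digitorum"),
    stringsAsFactors = FALSE
  )
}

# Run code with a local RNG state: seeds reproducibly, restores the caller's
# .Random.seed afterwards so library use never perturbs user randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation so that independent components (signal
# generation, fold shuffling, subject variability) draw from named substreams
# of one root seed. Kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset)) %% 2147483647)
}
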