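# Flash protocol: the nine-strength randomized light-adapted series plus the
# ISCEV standard LA 3.0 flash.

.LOG_FLASHES <- c(-0.367, -0.119, 0.114, 0.398, 0.602, 0.799, 0.949, 1.114, 1.204)
.LA3_LINEAR <- 3.0  # cd.s.m^-2, ISCEV light-adapted standard flash

#' Build a flash protocol table
#'
#' A flash protocol is a data.frame with one row per stimulus, columns
#' `log_strength` (log10 photopic cd.s.m^-2), `linear_strength`
#' (photopic cd.s.m^-2, `10^log_strength`), `background_cd_m2` and
#' `is_iscev_la3`. Rows are kept in canonical order of increasing strength
#' (randomized presentation order is a property of the recording session, not
#' of the canonical protocol).
#'
#' @param log_strength numeric vector of log10 flash strengths.
#' @param background_cd_m2 background luminance per flash (recycled).
#' @param is_iscev_la3 logical flag per flash (recycled).
#' @param randomized logical; whether flashes are presented in random order.
#' @param repeats_per_flash trials averaged per flash (metadata only).
#' @return data.frame with attributes `randomized` and `repeats_per_flash`.
#' @examples
#' flashProtocol(c(0, 1))
#' @export
flashProtocol <- function(log_strength, background_cd_m2 = 40,
                          is_iscev_la3 = FALSE, randomized = TRUE,
                          repeats_per_flash = 60L) {
  stopifnot(is.numeric(log_strength), length(log_strength) >= 1)
  o <- order(log_strength)
  p <- data.frame(
    log_strength = log_strength[o],
    linear_strength = 10^log_strength[o],
    background_cd_m2 = rep_len(background_cd_m2, length(log_strength))[o],
    is_iscev_la3 = rep_len(is_iscev_la3, length(log_strength))[o])
  if (any(p$linear_strength <= 0)) stop("flash strengths must be positive")
  attr(p, "randomized") <- randomized
  attr(p, "repeats_per_flash") <- as.integer(repeats_per_flash)
  p
}

#' Default light-adapted flash protocol
#'
#' Nine randomized flash strengths from -0.367 to 1.204 log photopic
#' cd.s.m^-2 on a 40 cd.m^-2 white background, followed by the ISCEV standard
#' light-adapted 3.0 cd.s.m^-2 flash (log10 strength 0.477) on a 30 cd.m^-2
#' background.
#'
#' @param include_la3 include the ISCEV LA3 flash (default TRUE).
#' @return a flash protocol data.frame (see [flashProtocol()]).
#' @examples
#' defaultFlashProtocol()
#' @export
defaultFlashProtocol <- function(include_la3 = TRUE) {
  p <- flashProtocol(.LOG_FLASHES, background_cd_m2 = 40,
                     is_iscev_la3 = FALSE, randomized = TRUE,
                     repeats_per_flash = 60L)
  if (include_la3) {
    la3 <- flashProtocol(log10(.LA3_LINEAR), background_cd_m2 = 30,
                         is_iscev_la3 = TRUE, randomized = FALSE,
                         repeats_per_flash = 30L)
    att <- attributes(p)[c("randomized", "repeats_per_flash")]
    p <- rbind(p, la3)
    p <- p[order(p$log_strength), ]
    rownames(p) <- NULL
    attr(p, "randomized") <- att$randomized
    attr(p, "repeats_per_flash") <- att$repeats_per_flash
  }
  p
}
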