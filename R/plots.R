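#' Plot the permutation null with observed and expected markers
#'
#' A histogram of the permuted overlap counts (gray) with a fitted normal
#' curve, the null mean marked in red (the expected count) and the observed
#' count in green — observed to the right of the null indicates enrichment.
#'
#' @param result a [PermTestResult-class].
#' @param main plot title.
#' @return `result`, invisibly.
#' @importFrom graphics abline curve hist legend
#' @importFrom grDevices png dev.off
#' @export
plotPermTest <- function(result, main = "Overlap permutation test") {
    null <- nullDistribution(result)
    xlim <- range(c(null, result@observed))
    h <- graphics::hist(null, breaks = 30, col = "gray", border = "white",
        freq = FALSE, xlim = xlim + c(-0.5, 0.5),
        xlab = "overlap count", main = main)
    if (result@permSd > 0)
        graphics::curve(stats::dnorm(x, result@permMean, result@permSd),
                        add = TRUE, lwd = 1)
    graphics::abline(v = result@permMean, col = "red", lwd = 2)
    graphics::abline(v = result@observed, col = "darkgreen", lwd = 2)
    graphics::legend("topright", bty = "n",
        legend = c(sprintf("observed = %d", result@observed),
                   sprintf("expected = %.2f", result@permMean),
                   sprintf("p = %.4g, z = %.2f", result@pValue,
                           result@zScore)),
        text.col = c("darkgreen", "red", "black"))
    invisible(result)
}

#' Plot a local z-score displacement profile
#'
#' @param profile a [LocalZProfile-class].
#' @param main plot title.
#' @return `profile`, invisibly.
#' @importFrom graphics plot
#' @importFrom stats dnorm
#' @export
plotLocalZ <- function(profile, main = "Local z-score profile") {
    graphics::plot(profile@shifts, profile@z, type = "b", pch = 16,
        xlab = "window displacement (bp)", ylab = "z-score", main = main)
    graphics::abline(v = 0, lty = 2)
    graphics::abline(h = 0, col = "gray")
    invisible(profile)
}
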