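#' Dosage-quotient scatter plot
#'
#' One point per amplicon (panel order) coloured by multiplex, with the
#' deletion/normal/duplication band boundaries drawn as dashed lines --
#' the visual used to read off exon losses and duplications.
#'
#' @param dq data.table from [compute_dq()].
#' @param bands list from [dq_bands()].
#' @param main plot title.
#' @return invisibly, the plotted data.
#' @export
plot_dq <- function(dq, bands = dq_bands(), main = "dosage quotients") {
  mux <- factor(dq$multiplex)
  graphics::plot(seq_len(nrow(dq)), dq$dq, col = as.integer(mux), pch = 19,
                 xlab = "amplicon index", ylab = "DQ", ylim = c(0, 2),
                 main = main)
  graphics::abline(h = c(bands$deletion_max, bands$normal_min,
                         bands$normal_max, bands$duplication_min),
                   lty = 2, col = "grey50")
  graphics::legend("topright", legend = levels(mux), col = seq_along(levels(mux)),
                   pch = 19, cex = 0.8, bty = "n")
  invisible(dq)
}
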