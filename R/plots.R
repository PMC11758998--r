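#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_vline labs
#'   theme_bw scale_colour_brewer
NULL

CLASS_COLOURS <- c(CHO = "#2E8B57", CHNO = "#7B3294", CHNOS = "#E6AB02",
                   CHOS = "#D7301F", other = "#35B9C9")

#' Van Krevelen diagram
#'
#' H/C against O/C, coloured by compound class; the dashed line at
#' H/C = 1.5 separates aliphatic-leaning from unsaturated molecules.
#'
#' @param descriptors table from [computeDescriptors()].
#' @return a ggplot object.
#' @export
plotVanKrevelen <- function(descriptors) {
  ggplot(descriptors, aes(x = oc_ratio, y = hc_ratio, colour = compound_class)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = 1.5, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = CLASS_COLOURS, name = "class") +
    labs(x = "O/C", y = "H/C") +
    theme_bw()
}

#' Kroll diagram
#'
#' Average carbon oxidation state against carbon number, coloured by
#' compound class.
#'
#' @param descriptors table from [computeDescriptors()].
#' @return a ggplot object.
#' @export
plotKroll <- function(descriptors) {
  ggplot(descriptors, aes(x = nC, y = osc, colour = compound_class)) +
    geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = CLASS_COLOURS, name = "class") +
    labs(x = "number of carbon atoms", y = "average carbon oxidation state") +
    theme_bw()
}

#' Clustergram-style heat map
#'
#' Molecules x time-bin z-scores with the Ward dendrogram on the rows,
#' annotated by cluster label; the colour scale saturates at |z| = 3.
#'
#' @param z z-score matrix from [zscoreRows()].
#' @param clustering a [MoleculeClustering].
#' @param file optional PNG path; NULL draws to the active device.
#' @return invisibly, the pheatmap object.
#' @export
plotClusterHeatmap <- function(z, clustering, file = NULL) {
  labels <- clusterLabels(clustering)
  zz <- z[names(labels), , drop = FALSE]
  zz[is.na(zz)] <- 0
  zz[zz > 3] <- 3; zz[zz < -3] <- -3
  ann <- data.frame(cluster = labels, row.names = names(labels))
  ph <- pheatmap::pheatmap(
    zz, cluster_cols = FALSE,
    clustering_method = "ward.D2",
    annotation_row = ann, show_rownames = FALSE,
    color = grDevices::colorRampPalette(c("#08306B", "white", "#67000D"))(61),
    breaks = seq(-3, 3, length.out = 62),
    filename = if (is.null(file)) NA else file,
    silent = !is.null(file))
  invisible(ph)
}

# quiet notes about ggplot2 column references
utils::globalVariables(c("oc_ratio", "hc_ratio", "compound_class", "nC", "osc"))
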