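#' Group-level mean co-occurrence matrix
#'
#' Elementwise mean of the binary response matrices of a set of participants:
#' entry (i, j) is the fraction of the group who sorted items i and j into
#' the same cluster (0 = never, 1 = always). For the default manifest this is
#' the 30 x 30 matrix used to visualise mean sorting behaviour per listener
#' group.
#'
#' @param responses non-empty list of [sorting_response()] objects (one
#'   group).
#' @param manifest a [generate_manifest()] manifest.
#' @param label group label carried on the result.
#' @return A numeric matrix of class `mean_cooccurrence` with entries in
#'   \[0, 1\], attributes `n` (contributing participants) and `label`.
#' @export
mean_cooccurrence <- function(responses, manifest, label = "group") {
  if (!length(responses)) stop("cannot aggregate an empty group")
  mats <- lapply(responses, build_response_matrix, manifest = manifest)
  m <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  attr(m, "talker_id") <- attr(mats[[1]], "talker_id")
  attr(m, "n") <- length(mats)
  attr(m, "label") <- label
  class(m) <- c("mean_cooccurrence", class(m))
  m
}

#' @export
print.mean_cooccurrence <- function(x, ...) {
  cat(sprintf("Mean co-occurrence matrix '%s': %d x %d items, n = %d participants\n",
              attr(x, "label"), nrow(x), ncol(x), attr(x, "n")))
  invisible(x)
}

#' Heatmap of a mean co-occurrence matrix
#'
#' Pure rendering of the matrix (no recomputation): items in manifest order,
#' so same-talker blocks sit on the diagonal; darker cells mark pairs the
#' group co-clustered more often.
#'
#' @param x a [mean_cooccurrence()] matrix.
#' @param main title; defaults to the group label.
#' @param ... passed to [graphics::image()].
#' @export
plot.mean_cooccurrence <- function(x, main = attr(x, "label"), ...) {
  n <- nrow(x)
  z <- t(unclass(x))[, n:1]
  graphics::image(seq_len(n), seq_len(n), z, zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("%s (n = %d)", main, attr(x, "n")), ...)
  graphics::axis(1, at = seq_len(n), labels = rownames(x), las = 2,
                 cex.axis = 0.4, tick = FALSE)
  graphics::axis(2, at = rev(seq_len(n)), labels = rownames(x), las = 2,
                 cex.axis = 0.4, tick = FALSE)
  graphics::box()
  invisible(x)
}
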