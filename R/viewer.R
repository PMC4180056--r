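# Overlap viewer: novel candidates ordered by originating-sequence length,
# with percentile guides and one colored coverage track per comparison set.

#' Lay out candidates for the overlap viewer
#'
#' Candidates are sorted ascending by the length of their originating contig
#' or scaffold (ties by candidate id, stable), so candidates from short
#' contigs sit left of those from long scaffolds. Each candidate occupies a
#' horizontal extent proportional to its base count; dashed percentile
#' guides are placed at the requested quantiles of the origin-length rank.
#'
#' @param candidates Candidate data frame from [extract_candidates()].
#' @param percentiles Quantile fractions for the guides (default deciles).
#' @return List with `layout` (candidates plus `x0`/`x1` columns) and
#'   `ticks` (data frame `fraction`, `x`). Empty input warns and returns an
#'   empty layout.
#' @export
layout_candidates <- function(candidates, percentiles = seq(0.1, 0.9, by = 0.1)) {
  if (nrow(candidates) == 0L) {
    warning("no candidates to lay out", call. = FALSE)
    return(list(layout = cbind(candidates, x0 = numeric(0), x1 = numeric(0)),
                ticks = data.frame(fraction = numeric(0), x = numeric(0))))
  }
  ord <- order(candidates$origin_length, candidates$candidate_id, method = "radix")
  lay <- candidates[ord, , drop = FALSE]
  w <- candidate_len(lay)
  lay$x1 <- cumsum(as.double(w))
  lay$x0 <- lay$x1 - w
  n <- nrow(lay)
  idx <- pmax(1L, ceiling(percentiles * n))
  ticks <- data.frame(fraction = percentiles, x = lay$x1[idx])
  rownames(lay) <- NULL
  list(layout = lay, ticks = ticks)
}

#' Per-candidate coverage track for one comparison set
#'
#' Coverage is the fraction of each candidate's bases overlapped by the
#' set's masks (original-candidate-local coordinates, the same parsed files
#' used for filtering).
#'
#' @param candidates Candidate data frame.
#' @param masks Parsed mask data frame (`query_id`, `start`, `end`).
#' @param label Track name.
#' @param color Track color.
#' @return An `overlap_track`: list with `label`, `color` and per-candidate
#'   `covered` fractions in `[0, 1]` (candidate order preserved).
#' @export
overlap_track <- function(candidates, masks, label, color = "steelblue") {
  covered <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    m <- masks[masks$query_id == candidates$candidate_id[i], , drop = FALSE]
    if (nrow(m) == 0L) next
    cur <- IRanges::IRanges(candidates$local_start[i] + 1L, candidates$local_end[i])
    mr <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
    covered[i] <- sum(IRanges::width(IRanges::intersect(cur, mr))) /
      (candidates$local_end[i] - candidates$local_start[i])
  }
  structure(list(label = label, color = color, covered = covered),
            class = "overlap_track")
}

#' Render the candidate-overlap comparison figure
#'
#' One row per track; within a row each candidate is drawn as a bar whose
#' height is that track's coverage fraction, so runs of candidates covered
#' by no track show up as visibly empty columns — the signature of
#' contaminant sequence. Dashed verticals mark the origin-length
#' percentiles. PNG and SVG output are supported, chosen from the file
#' extension.
#'
#' @param layout Result of [layout_candidates()].
#' @param tracks List of [overlap_track()] objects (candidates must be in
#'   layout order).
#' @param path Output path ending in `.png` or `.svg`.
#' @param width,height Canvas size in pixels (PNG) or inches/100 (SVG).
#' @return `path`, invisibly.
#' @export
render_overlap_plot <- function(layout, tracks, path, width = 900, height = NULL) {
  if (length(tracks) == 0L) stop("at least one track is required")
  lay <- layout$layout
  nt <- length(tracks)
  if (is.null(height)) height <- 110 * nt + 60
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = width, height = height, type = "cairo")
  } else if (ext == "svg") {
    grDevices::svg(path, width = width / 100, height = height / 100)
  } else stop(sprintf("unsupported image format '.%s' (use .png or .svg)", ext))
  on.exit(grDevices::dev.off())
  total <- if (nrow(lay) > 0L) max(lay$x1) else 1
  graphics::par(mar = c(3.5, 7, 1.5, 1))
  graphics::plot(NULL, xlim = c(0, total), ylim = c(0, nt), xaxs = "i",
                 yaxs = "i", axes = FALSE, xlab = "", ylab = "")
  for (t in seq_len(nt)) {
    tr <- tracks[[t]]
    y0 <- nt - t
    graphics::abline(h = y0, col = "grey80")
    keep <- which(tr$covered > 0)
    if (nrow(lay) > 0L && length(keep) > 0L)
      graphics::rect(lay$x0[keep], y0, lay$x1[keep],
                     y0 + 0.9 * pmin(1, tr$covered[keep]),
                     col = tr$color, border = NA)
    graphics::mtext(tr$label, side = 2, at = y0 + 0.45, las = 1, cex = 0.9)
  }
  if (nrow(layout$ticks) > 0L)
    graphics::abline(v = layout$ticks$x, lty = 2, col = "grey40")
  graphics::axis(1, at = layout$ticks$x,
                 labels = sprintf("%d%%", round(100 * layout$ticks$fraction)),
                 cex.axis = 0.8)
  graphics::mtext("candidates, ascending origin sequence length", side = 1, line = 2.2,
                  cex = 0.9)
  graphics::box()
  invisible(path)
}
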