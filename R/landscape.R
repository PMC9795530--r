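# Genome-wide recombination landscape: crossover events binned into fixed
# windows (1 Mb by default) on original coordinates, autosomes only.

#' Bin crossover events into a fixed-window recombination landscape
#'
#' Each event is assigned to the window containing its interval midpoint
#' (midpoint assignment avoids double-counting switch intervals spanning a
#' window edge; \code{method = "overlap"} instead adds each overlapped
#' window's covered fraction).  Sex chromosomes pair only in the
#' pseudoautosomal region and are excluded by default.  Windows tile every
#' chromosome; the final partial window is retained with its true length.
#'
#' @param calls Crossover call table with original-coordinate columns
#'   \code{chrom}, \code{orig_start}, \code{orig_end} (e.g. the kept table
#'   from [filter_by_coverage()]).
#' @param chrom_sizes Named integer vector of original chromosome lengths,
#'   or a two-column chrom.sizes file path.
#' @param window_size Window width in bases (default 1e6).
#' @param exclude Chromosome names to omit (default the sex chromosomes).
#' @param method \code{"midpoint"} (default) or \code{"overlap"}.
#' @return data.frame of class \code{landscape_table} with columns
#'   \code{chrom}, \code{window_start}, \code{window_end}, \code{count},
#'   sorted by (chrom, window_start).
#' @export
build_landscape <- function(calls, chrom_sizes, window_size = 1e6,
                            exclude = c("X", "Y", "chrX", "chrY"),
                            method = c("midpoint", "overlap")) {
  method <- match.arg(method)
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    cs <- read.table(chrom_sizes, sep = "\t", header = FALSE,
                     col.names = c("chrom", "size"),
                     colClasses = c("character", "integer"))
    chrom_sizes <- setNames(cs$size, cs$chrom)
  }
  window_size <- as.integer(window_size)
  keep_chr <- setdiff(names(chrom_sizes), exclude)
  ev <- calls[calls$chrom %in% keep_chr, , drop = FALSE]
  if (nrow(ev) && (anyNA(ev$orig_start) || anyNA(ev$orig_end)))
    stop("calls lack original coordinates; lift them first")
  rows <- lapply(keep_chr, function(ch) {
    size <- chrom_sizes[[ch]]
    nw <- max(1L, as.integer(ceiling(size / window_size)))
    ws <- (seq_len(nw) - 1L) * window_size
    we <- pmin(ws + window_size, size)
    e <- ev[ev$chrom == ch, , drop = FALSE]
    if (nrow(e) && (any(e$orig_end > size) | any(e$orig_start < 0L)))
      stop("event beyond chromosome end on ", ch,
           " (liftover or chrom.sizes mismatch)")
    if (method == "midpoint") {
      mid <- (e$orig_start + e$orig_end) / 2
      wi <- pmin(as.integer(mid %/% window_size), nw - 1L)
      cnt <- tabulate(wi + 1L, nbins = nw)
    } else {
      cnt <- numeric(nw)
      for (i in seq_len(nrow(e))) {
        w0 <- as.integer(e$orig_start[i] %/% window_size)
        w1 <- as.integer(max(e$orig_start[i], e$orig_end[i] - 1L) %/% window_size)
        ov <- pmin(we[(w0:w1) + 1L], e$orig_end[i]) -
          pmax(ws[(w0:w1) + 1L], e$orig_start[i])
        cnt[(w0:w1) + 1L] <- cnt[(w0:w1) + 1L] +
          ov / max(1L, e$orig_end[i] - e$orig_start[i])
      }
    }
    data.frame(chrom = ch, window_start = ws, window_end = we, count = cnt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("landscape_table", "data.frame")
  out
}

#' Plot the recombination landscape
#'
#' One histogram panel per chromosome: crossover count per window along the
#' chromosome.
#'
#' @param table A \code{landscape_table} from [build_landscape()].
#' @param out_image PNG output path.
#' @param width,height Image size in pixels (height is per panel).
#' @return Invisibly, the plotted table.
#' @export
plot_landscape <- function(table, out_image, width = 900L, height = 220L) {
  if (nrow(table) == 0L) stop("landscape table is empty; nothing to plot")
  chroms <- unique(table$chrom)
  grDevices::png(out_image, width = width, height = height * length(chroms))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(chroms), 1L), mar = c(3.5, 4, 2, 1))
  for (ch in chroms) {
    t <- table[table$chrom == ch, , drop = FALSE]
    graphics::barplot(t$count, names.arg = round(t$window_start / 1e6, 1),
                      col = "grey35", border = NA, space = 0,
                      main = ch, xlab = "", ylab = "crossovers / window",
                      cex.names = 0.7)
    graphics::mtext("window start (Mb)", side = 1, line = 2.2, cex = 0.8)
  }
  invisible(table)
}
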