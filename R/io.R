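#' @include AllClasses.R
NULL

#' Write / read a movie as multi-page TIFF with a channel-plan sidecar
#'
#' The movie is stored as one 16-bit multi-page TIFF (counts clamped to
#' 65535) plus a tab-separated sidecar describing the frame rate and the
#' channel plan, so a movie round-trips through disk to within integer
#' rounding of the camera counts.
#'
#' @param stack an \code{\link{ImageStack}}.
#' @param path TIFF path; the sidecar is written next to it as
#'   \code{<path>.plan.tsv}.
#' @return \code{writeMovie} returns \code{path} invisibly;
#'   \code{readMovie} returns an \code{ImageStack}.
#' @export
writeMovie <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  pages <- lapply(seq_len(nFrames(stack)), function(f)
    pmin(round(stack@data[, , f]), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- paste0(path, ".plan.tsv")
  con <- file(side, "w")
  writeLines(paste0("# frameRate\t", format(stack@frameRate, digits = 17)),
             con)
  utils::write.table(stack@plan, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeMovie
#' @export
readMovie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".plan.tsv")
  lines <- readLines(side)
  fr <- as.numeric(sub("^# frameRate\t", "", lines[1]))
  plan <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  dat <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) dat[, , f] <- pages[[f]][, , drop = TRUE] * 65535
  ImageStack(dat, plan, fr)
}

#' Write / read tabular pipeline outputs as TSV
#'
#' Thin wrappers used for spot tables, ground-truth emitter tables and
#' complex tables.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return \code{writeTsv} returns \code{path} invisibly; \code{readTsv}
#'   returns a data.frame.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write / read a StepHistogram as TSV
#'
#' One row per step class plus the condition label and totals in comment
#' headers.
#'
#' @param hist a \code{\link{StepHistogram}}.
#' @param path file path.
#' @return \code{writeStepHistogram} returns \code{path} invisibly;
#'   \code{readStepHistogram} returns a \code{StepHistogram}.
#' @export
writeStepHistogram <- function(hist, path) {
  stopifnot(is(hist, "StepHistogram"))
  con <- file(path, "w")
  writeLines(c(paste0("# condition\t", hist@condition),
               paste0("# totalRna\t", hist@totalRna)), con)
  utils::write.table(data.frame(class = names(hist@counts),
                                count = as.integer(hist@counts)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeStepHistogram
#' @export
readStepHistogram <- function(path) {
  lines <- readLines(path)
  condition <- sub("^# condition\t", "", lines[1])
  totalRna <- as.integer(sub("^# totalRna\t", "", lines[2]))
  tab <- utils::read.table(text = lines[-(1:2)], sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer"))
  StepHistogram(setNames(tab$count, tab$class), totalRna = totalRna,
                condition = condition)
}
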