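## Grid helpers shared across modules. Internal except where noted.

#' Translate a matrix by an integer pixel offset
#'
#' Content moves \code{dx} columns rightwards (east) and \code{dy} rows
#' downwards (south); exposed margins are filled with \code{fill}.
#'
#' @param m matrix.
#' @param dx,dy integer offsets.
#' @param fill fill value for exposed margins.
#' @return matrix of identical dimensions.
#' @export
shiftContent <- function(m, dx, dy, fill = NA) {
  stopifnot(is.matrix(m), dx == round(dx), dy == round(dy))
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  srcRows <- seq_len(nr) - dy
  srcCols <- seq_len(nc) - dx
  okR <- srcRows >= 1L & srcRows <= nr
  okC <- srcCols >= 1L & srcCols <= nc
  if (any(okR) && any(okC))
    out[which(okR), which(okC)] <- m[srcRows[okR], srcCols[okC], drop = FALSE]
  out
}

## Block-wise sums of a matrix over origin-aligned block x block windows.
## Partial edge blocks aggregate whatever pixels exist.
blockSum <- function(m, block) {
  rg <- (seq_len(nrow(m)) - 1L) %/% block + 1L
  cg <- (seq_len(ncol(m)) - 1L) %/% block + 1L
  s <- rowsum(m, rg, reorder = TRUE)
  t(rowsum(t(s), cg, reorder = TRUE))
}

## Block-wise mean ignoring NA; blocks with no finite pixel give NA.
blockMeanNA <- function(m, block) {
  ok <- !is.na(m)
  m0 <- m
  m0[!ok] <- 0
  s <- blockSum(m0, block)
  n <- blockSum(ok * 1, block)
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

## Count of non-NA pixels per block.
blockCountValid <- function(m, block) {
  blockSum((!is.na(m)) * 1, block)
}

## Random blob mask built from overlapping discs until the requested area
## fraction is covered. Used for clouds and their shadows.
makeBlobMask <- function(nr, nc, fraction, rMin = 3, rMax = 8) {
  mask <- matrix(FALSE, nr, nc)
  if (fraction <= 0) return(mask)
  if (fraction >= 1) return(!mask)
  target <- fraction * nr * nc
  rows <- row(mask); cols <- col(mask)
  guard <- 0L
  while (sum(mask) < target && guard < 10000L) {
    cr <- runif(1, 1, nr); cc <- runif(1, 1, nc)
    rad <- runif(1, rMin, rMax)
    mask <- mask | ((rows - cr)^2 + (cols - cc)^2 <= rad^2)
    guard <- guard + 1L
  }
  mask
}

#' Month membership of a season window
#'
#' Season windows are inclusive calendar-month intervals
#' \code{c(startMonth, endMonth)} that may wrap the year end (e.g. the
#' November--April 'winter').
#'
#' @param window integer vector \code{c(start, end)} of months in 1..12.
#' @return integer vector of member months.
#' @export
windowMonths <- function(window) {
  s <- as.integer(window[1]); e <- as.integer(window[2])
  stopifnot(s >= 1, s <= 12, e >= 1, e <= 12)
  if (s <= e) s:e else c(s:12, 1:e)
}

#' Assign a date to a season
#'
#' @param date a \code{Date} (or vector of dates).
#' @param seasonWindows named list of \code{c(startMonth, endMonth)}.
#' @return character vector of season labels; \code{NA} where the date's
#'   month falls in no window.
#' @export
seasonForDate <- function(date, seasonWindows) {
  m <- as.integer(format(as.Date(date), "%m"))
  lut <- rep(NA_character_, 12L)
  for (nm in names(seasonWindows)) lut[windowMonths(seasonWindows[[nm]])] <- nm
  lut[m]
}

## Check that season windows do not overlap in month membership.
checkSeasonWindows <- function(seasonWindows) {
  months <- unlist(lapply(seasonWindows, windowMonths))
  if (anyDuplicated(months))
    stop("season windows overlap in months: ",
         paste(unique(months[duplicated(months)]), collapse = ", "))
  invisible(TRUE)
}

## Fraction of pixels flagged valid.
validFraction <- function(pass) mean(pass@valid)

## Derive a stream of sub-seeds from one integer seed, kept below 2^31.
deriveSeeds <- function(seed, n) {
  (as.integer(seed) + 1013L * seq_len(n)) %% .Machine$integer.max
}
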