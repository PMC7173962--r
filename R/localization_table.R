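#' Construct a localization table
#'
#' The canonical data product of single-molecule localization microscopy:
#' one row per detected fluorophore emission. Coordinates are continuous
#' nanometres (origin arbitrary, +x right, +y up); frames are 0-based.
#'
#' @param frame integer vector of 0-based acquisition frame indices.
#' @param channel character vector of channel/label identifiers (recycled).
#' @param x,y numeric coordinates in nm.
#' @param photons photon counts (recycled; default 1000).
#' @param uncertainty per-localization precision in nm (recycled; default NA).
#' @return A `data.frame` of class `localization_table` with columns
#'   `frame`, `channel`, `x`, `y`, `photons`, `uncertainty`.
#' @export
localization_table <- function(frame = integer(), channel = character(),
                               x = numeric(), y = numeric(),
                               photons = 1000, uncertainty = NA_real_) {
  n <- length(x)
  stopifnot(length(y) == n, length(frame) %in% c(1L, n) || n == 0L)
  tab <- data.frame(
    frame = as.integer(rep_len(frame, n)),
    channel = as.character(rep_len(channel, n)),
    x = as.numeric(x),
    y = as.numeric(y),
    photons = as.numeric(rep_len(photons, n)),
    uncertainty = as.numeric(rep_len(uncertainty, n)),
    stringsAsFactors = FALSE
  )
  validate_localization_table(tab)
}

#' @rdname localization_table
#' @param tab a data.frame to validate.
#' @export
validate_localization_table <- function(tab) {
  need <- c("frame", "channel", "x", "y", "photons", "uncertainty")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("localization table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) > 0L) {
    if (any(!is.finite(tab$x)) || any(!is.finite(tab$y))) {
      stop("localization table contains non-finite coordinates")
    }
    if (any(tab$frame < 0L)) stop("frame indices must be >= 0")
  }
  class(tab) <- unique(c("localization_table", class(tab)))
  tab
}

# column-name mappings for supported CSV dialects
.dialects <- list(
  thunderstorm = c(frame = "frame", channel = "channel",
                   x = "x [nm]", y = "y [nm]",
                   photons = "intensity [photon]",
                   uncertainty = "uncertainty [nm]"),
  generic = c(frame = "frame", channel = "channel", x = "x", y = "y",
              photons = "photons", uncertainty = "uncertainty")
)

#' Read a localization CSV file
#'
#' Supports the ThunderSTORM-style header (`"x [nm]"`, `"intensity [photon]"`,
#' ...) and a plain `generic` header. Units are nm throughout. Rows with
#' non-numeric coordinates are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @param dialect one of `"thunderstorm"`, `"generic"`.
#' @return a [localization_table()].
#' @export
read_localizations <- function(path, dialect = c("thunderstorm", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  map <- .dialects[[dialect]]
  missing_cols <- setdiff(unname(map[c("frame", "x", "y")]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s) for dialect '", dialect, "': ",
         paste(missing_cols, collapse = ", "))
  }
  get <- function(field, default) {
    cn <- map[[field]]
    if (cn %in% names(raw)) raw[[cn]] else rep(default, nrow(raw))
  }
  xs <- suppressWarnings(as.numeric(get("x", NA)))
  ys <- suppressWarnings(as.numeric(get("y", NA)))
  fr <- suppressWarnings(as.integer(get("frame", NA)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(fr))
  if (length(bad) > 0L) {
    stop("malformed (non-numeric) rows at file line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  localization_table(
    frame = fr,
    channel = as.character(get("channel", "0")),
    x = xs, y = ys,
    photons = suppressWarnings(as.numeric(get("photons", NA))),
    uncertainty = suppressWarnings(as.numeric(get("uncertainty", NA)))
  )
}

#' Write a localization table as CSV
#'
#' @param tab a [localization_table()].
#' @param path output path.
#' @param dialect header style, as in [read_localizations()].
#' @return `path`, invisibly.
#' @export
write_localizations <- function(tab, path,
                                dialect = c("thunderstorm", "generic")) {
  dialect <- match.arg(dialect)
  tab <- validate_localization_table(tab)
  map <- .dialects[[dialect]]
  out <- tab[, names(map)]
  names(out) <- unname(map)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Render localizations as a 2D histogram image
#'
#' Accumulates localizations into square pixels and optionally applies a
#' Gaussian blur. Total intensity equals the number of localizations inside
#' the rendered extent (blur conserves mass up to truncation at the border).
#'
#' @param tab a [localization_table()] (all rows rendered; filter first).
#' @param pixel_nm pixel size in nm (default 10).
#' @param blur_sd_nm Gaussian blur sd in nm; 0 disables blurring.
#' @param xlim,ylim numeric length-2 extents in nm; default data range padded
#'   by 4 blur sd.
#' @return numeric matrix (rows = y, columns = x) with attributes
#'   `xlim`, `ylim`, `pixel_nm`.
#' @export
render_image <- function(tab, pixel_nm = 10, blur_sd_nm = 0,
                         xlim = NULL, ylim = NULL) {
  if (nrow(tab) == 0L) stop("cannot render an empty localization table")
  pad <- 4 * blur_sd_nm + pixel_nm
  if (is.null(xlim)) xlim <- range(tab$x) + c(-pad, pad)
  if (is.null(ylim)) ylim <- range(tab$y) + c(-pad, pad)
  nx <- max(1L, ceiling(diff(xlim) / pixel_nm))
  ny <- max(1L, ceiling(diff(ylim) / pixel_nm))
  ix <- floor((tab$x - xlim[1]) / pixel_nm) + 1L
  iy <- floor((tab$y - ylim[1]) / pixel_nm) + 1L
  keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  img <- matrix(0, nrow = ny, ncol = nx)
  if (any(keep)) {
    counts <- table(factor(iy[keep], levels = seq_len(ny)),
                    factor(ix[keep], levels = seq_len(nx)))
    img <- matrix(as.numeric(counts), nrow = ny, ncol = nx)
  }
  if (blur_sd_nm > 0) img <- gaussian_blur(img, blur_sd_nm / pixel_nm)
  attr(img, "xlim") <- xlim
  attr(img, "ylim") <- ylim
  attr(img, "pixel_nm") <- pixel_nm
  img
}

# separable Gaussian convolution with zero padding; kernel normalized to 1 so
# mass is conserved for signal further than the kernel half-width from edges
gaussian_blur <- function(img, sd_px) {
  half <- max(1L, ceiling(4 * sd_px))
  k <- stats::dnorm(seq(-half, half), sd = sd_px)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    padded <- c(numeric(half), v, numeric(half))
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- sum(padded[i:(i + 2L * half)] * rev(k))
    out
  }
  tmp <- apply(img, 2L, conv1)        # along y
  t(apply(tmp, 1L, conv1))            # along x
}
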