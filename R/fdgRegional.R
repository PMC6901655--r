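#' Default wall assignment of the 17-segment bullseye
#'
#' Maps AHA segments to four walls, excluding the apical cap: septal
#' segments 2, 3, 8, 9, 14 (anteroseptal + inferoseptal), lateral 5, 6,
#' 11, 12, 16 (inferolateral + anterolateral), anterior 1, 7, 13,
#' inferior 4, 10, 15; segment 17 is always excluded.
#'
#' @return character vector of length 17 with values `"septal"`,
#'   `"lateral"`, `"anterior"`, `"inferior"`, `"excluded"`; names are
#'   segment numbers.
#' @examples
#' table(defaultWallRegions())
#' @export
defaultWallRegions <- function() {
  m <- rep(NA_character_, 17)
  m[c(2, 3, 8, 9, 14)] <- "septal"
  m[c(5, 6, 11, 12, 16)] <- "lateral"
  m[c(1, 7, 13)] <- "anterior"
  m[c(4, 10, 15)] <- "inferior"
  m[17] <- "excluded"
  names(m) <- as.character(1:17)
  m
}

.checkRegions <- function(regions) {
  if (length(regions) != 17L)
    stop("wall mapping must assign all 17 segments")
  if (regions[17] != "excluded")
    stop("segment 17 (apical cap) must be excluded")
  ok <- c("septal", "lateral", "anterior", "inferior", "excluded")
  if (any(!regions %in% ok))
    stop("unknown wall label in mapping")
  if (any(regions[1:16] == "excluded"))
    stop("segments 1-16 must each be assigned to a wall")
  regions
}

#' Per-wall SUVmean of a 17-segment polar map
#'
#' Unweighted arithmetic mean of the segment values assigned to each
#' wall; the apical cap (segment 17) never contributes.
#'
#' @param map a [PolarMap17-class] or numeric vector of 17 segment SUVs.
#' @param regions segment-to-wall mapping as from [defaultWallRegions()].
#' @return named numeric: `septal`, `lateral`, `anterior`, `inferior`.
#' @examples
#' wallMeans(new("PolarMap17", values = as.numeric(1:17)))
#' @export
wallMeans <- function(map, regions = defaultWallRegions()) {
  if (is(map, "PolarMap17")) {
    validObject(map)
    v <- map@values
  } else {
    v <- as.numeric(map)
    if (length(v) != 17L) stop("a polar map needs exactly 17 segment values")
  }
  regions <- .checkRegions(regions)
  walls <- c("septal", "lateral", "anterior", "inferior")
  out <- vapply(walls, function(w) {
    idx <- which(regions == w)
    if (!length(idx)) stop("wall '", w, "' has no segments assigned")
    mean(v[idx])
  }, numeric(1))
  out
}

#' Septal-to-lateral FDG uptake ratio
#'
#' @param septalMean,lateralMean wall SUVmean values; the lateral value
#'   must be positive.
#' @return `septalMean / lateralMean`.
#' @examples
#' fdgSLR(5.58, 11.19)
#' @export
fdgSLR <- function(septalMean, lateralMean) {
  if (any(lateralMean <= 0))
    stop("lateral SUVmean must be positive to form a septal-to-lateral ratio")
  septalMean / lateralMean
}
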