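#' Landmark configuration constructor
#'
#' A landmark configuration is one specimen's ordered set of 2-D outline
#' landmarks. Landmark order is anatomically homologous across specimens:
#' index 1 is the anterior tip of the propterygium and index k the posterior
#' insertion of the fin onto the body. Coordinates follow the mathematical
#' convention (y increases upward); image-coordinate files can be converted
#' on read with `flip_y = TRUE`.
#'
#' @param coords numeric k x 2 matrix of (x, y) coordinates, in mm when a
#'   scale factor was applied, otherwise in pixels.
#' @param specimen_id character scalar identifying the specimen.
#' @param side `"left"` or `"right"`; which pectoral fin was digitized.
#' @param scale optional mm-per-unit scale factor that was already applied.
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(coords, specimen_id, side = "right", scale = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("coords must be a k x 2 matrix, got ", ncol(coords), " columns")
  if (nrow(coords) < 3L)
    stop("configuration '", specimen_id, "' has fewer than 3 landmarks")
  if (!all(is.finite(coords)))
    stop("configuration '", specimen_id, "' contains non-finite coordinates")
  side <- match.arg(side, c("right", "left"))
  structure(
    list(specimen_id = as.character(specimen_id), coords = unname(coords),
         k = nrow(coords), scale = scale, side = side),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config> ", x$specimen_id, ": ", x$k, " landmarks, ",
      x$side, " side\n", sep = "")
  invisible(x)
}

#' Read a TPS landmark file
#'
#' Parses the TPS dialect emitted by landmark-digitizing tools: records
#' starting with `LM=<count>`, followed by one `x y` line per landmark and
#' optional `ID=`, `IMAGE=` and `SCALE=` lines. Coordinates are multiplied by
#' the scale factor when one is present. `CURVES`/`POINTS` blocks are not
#' supported (outlines are stored as LM landmarks with a separate sliders
#' file).
#'
#' @param path path to a TPS file.
#' @param flip_y negate y coordinates on read; use for files digitized in
#'   image coordinates (y increasing downward).
#' @return list of [landmark_config] objects, one per record.
#' @export
read_tps <- function(path, flip_y = FALSE) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  configs <- list()
  i <- 1L
  n_rec <- 0L
  while (i <= length(lines)) {
    if (lines[i] == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop("TPS parse error at line ", i, ": expected LM= record header, got '",
           lines[i], "'")
    n_rec <- n_rec + 1L
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("TPS parse error: malformed LM count in record ", n_rec,
           " (line ", i, ")")
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      if (i > length(lines) || grepl("^(LM|ID|IMAGE|SCALE)\\s*=", lines[i],
                                     ignore.case = TRUE))
        stop("TPS parse error: record ", n_rec, " declares ", k,
             " landmarks but coordinate lines end early (line ", i, ")")
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (length(xy) != 2L || anyNA(xy))
        stop("TPS parse error: non-numeric coordinate at line ", i,
             " (record ", n_rec, ")")
      coords[j, ] <- xy
      i <- i + 1L
    }
    id <- as.character(n_rec)
    scale <- NULL
    while (i <= length(lines) && lines[i] != "" &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      ln <- lines[i]
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- trimws(sub("^ID\\s*=", "", ln, ignore.case = TRUE))
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- suppressWarnings(
          as.numeric(sub("^SCALE\\s*=", "", ln, ignore.case = TRUE)))
        if (is.na(scale))
          stop("TPS parse error: non-numeric SCALE at line ", i)
      } else if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE)) {
        # retained image filename is ignored
      } else {
        stop("TPS parse error: unexpected line ", i, " in record ", n_rec,
             ": '", ln, "' (extra coordinate lines beyond LM count?)")
      }
      i <- i + 1L
    }
    if (!is.null(scale)) coords <- coords * scale
    if (flip_y) coords[, 2L] <- -coords[, 2L]
    configs[[n_rec]] <- landmark_config(coords, id, scale = scale)
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Coordinates are written at fixed 6-decimal precision with no SCALE line
#' (coordinates are assumed to be in mm already).
#'
#' @param configs list of [landmark_config] objects sharing a landmark count.
#' @param path output path.
#' @export
write_tps <- function(configs, path) {
  if (length(configs) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  ks <- vapply(configs, function(c) c$k, integer(1))
  if (length(unique(ks)) != 1L)
    stop("all configurations must share the same landmark count; got k in {",
         paste(sort(unique(ks)), collapse = ", "), "}")
  out <- unlist(lapply(configs, function(cf) {
    c(sprintf("LM=%d", cf$k),
      sprintf("%.6f %.6f", cf$coords[, 1], cf$coords[, 2]),
      sprintf("ID=%s", cf$specimen_id))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Reflect a configuration across its bilateral (vertical) axis
#'
#' Left-side fins are reflected so that all fin margins face the same way
#' before superimposition. The x coordinates are negated and the
#' configuration re-centered so its centroid is unchanged; landmark order is
#' preserved, so anatomical homology is maintained. Applying the reflection
#' twice returns the original configuration.
#'
#' @param config a [landmark_config].
#' @return the reflected [landmark_config] with the side flag flipped.
#' @export
reflect_configuration <- function(config) {
  stopifnot(inherits(config, "landmark_config"))
  ctr <- colMeans(config$coords)
  coords <- config$coords
  coords[, 1L] <- -coords[, 1L] + 2 * ctr[1L]
  landmark_config(coords, config$specimen_id,
                  side = if (config$side == "left") "right" else "left",
                  scale = config$scale)
}

#' Read a sliding-semilandmark definition file
#'
#' Three whitespace-delimited integer columns (before, slider, after), one
#' row per sliding semilandmark, 1-based landmark indices. The two fixed
#' curve endpoints must never appear as sliders.
#'
#' @param path path to the sliders file.
#' @param k total landmark count, used to validate indices and to reject
#'   endpoint landmarks (1 and k) as sliders. If `NULL`, only structural
#'   checks are applied.
#' @return integer matrix with columns `before`, `slider`, `after`.
#' @export
read_sliders <- function(path, k = NULL) {
  if (!file.exists(path)) stop("sliders file not found: ", path)
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("before", "slider", "after"))
  m <- as.matrix(tab)
  storage.mode(m) <- "integer"
  validate_sliders(m, k)
  m
}

validate_sliders <- function(sliders, k = NULL) {
  if (ncol(sliders) != 3L) stop("sliders must have 3 columns")
  if (anyNA(sliders)) stop("sliders contain non-integer entries")
  mid <- sliders[, 2L]
  if (anyDuplicated(mid))
    stop("slider index ", mid[duplicated(mid)][1L],
         " appears more than once as a middle element")
  bad <- sliders[, 1L] == mid | sliders[, 3L] == mid |
    sliders[, 1L] == sliders[, 3L]
  if (any(bad))
    stop("degenerate slider triplet at row ", which(bad)[1L],
         ": before, slider, after must be distinct")
  if (!is.null(k)) {
    if (any(sliders < 1L | sliders > k))
      stop("slider indices out of range [1, ", k, "]")
    if (any(mid %in% c(1L, k)))
      stop("fixed endpoint landmarks (1 and ", k,
           ") may not be sliding semilandmarks")
  }
  invisible(sliders)
}

#' Read a specimen metadata table
#'
#' CSV with header
#' `specimen_id,species,sex,disc_width_mm,clasper_length_mm,maturity`.
#' Clasper length is empty/NA for females; maturity may be `immature`,
#' `mature` or `unknown`.
#'
#' @param path path to the CSV file.
#' @return a `data.frame` with validated columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "sex", "disc_width_mm",
            "clasper_length_mm", "maturity")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$specimen_id))
    stop("duplicate specimen_id: ",
         md$specimen_id[duplicated(md$specimen_id)][1L])
  if (!all(md$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (!all(is.finite(md$disc_width_mm)) || any(md$disc_width_mm <= 0))
    stop("disc_width_mm must be positive and finite")
  cl <- md$clasper_length_mm
  if (any(!is.na(cl) & cl < 0)) stop("clasper_length_mm must be >= 0")
  if (any(md$sex == "female" & !is.na(cl)))
    stop("females must have missing clasper_length_mm: ",
         md$specimen_id[md$sex == "female" & !is.na(cl)][1L])
  if (!all(md$maturity %in% c("immature", "mature", "unknown")))
    stop("maturity must be immature, mature or unknown")
  md
}

#' Read a rooted newick phylogeny with branch lengths
#'
#' Thin wrapper around [ape::read.tree] that enforces what the comparative
#' analyses need: unique leaf labels and branch lengths on every edge
#' (the Brownian-motion covariance in PGLS is built from shared path
#' lengths).
#'
#' @param path path to a newick file.
#' @return an [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (is.null(tree$edge.length))
    stop("newick tree has no branch lengths; PGLS requires them")
  if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  tree
}

# Stack a list of landmark_config objects into a k x 2 x n array.
configs_to_array <- function(configs) {
  ks <- vapply(configs, function(c) c$k, integer(1))
  if (length(unique(ks)) != 1L)
    stop("configurations have heterogeneous landmark counts")
  arr <- array(NA_real_, c(ks[1L], 2L, length(configs)),
               dimnames = list(NULL, c("x", "y"),
                               vapply(configs, function(c) c$specimen_id,
                                      character(1))))
  for (i in seq_along(configs)) arr[, , i] <- configs[[i]]$coords
  arr
}
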