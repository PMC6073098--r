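## Leaf physiognomy: the twenty size, shape and tooth variables derived from
## raw per-leaf measurements, species-level aggregation, the Ln(x+1)
## transform, and the Pearson trait correlation matrix.

#' Names of the twenty leaf physiognomy traits
#'
#' Order and naming used in every trait table produced by the package:
#' blade area `A` (cm^2), perimeter `P` (cm), internal perimeter `Pi` (cm,
#' perimeter after tooth removal), perimeter ratio `Pratio` (P/Pi),
#' compactness `Comp` (P^2/A), shape factor `ShapFact` (4*pi*A/P^2), major and
#' minor axis lengths `MajLen`, `MinLen` (cm), Feret diameter `FerDiam`
#' (diameter of the circle with the leaf's area, cm), `FerDiamRatio`
#' (FerDiam/MajLen), tooth area `TA` (cm^2), `TABA` (TA/A), `TA_P` (TA/P, cm),
#' `TA_Pi` (TA/Pi, cm), primary and secondary tooth counts `teeth1`,
#' `teeth2`, total count `n_teeth`, average tooth area `AvgTA` (TA/teeth1,
#' cm^2), and tooth densities `nteeth_P`, `nteeth_Pi` (counts per cm).
#'
#' @return Character vector of length 20.
#' @export
trait_names <- function() {
  c("A", "P", "Pi", "Pratio", "Comp", "ShapFact", "MajLen", "MinLen",
    "FerDiam", "FerDiamRatio", "TA", "TABA", "TA_P", "TA_Pi",
    "teeth1", "teeth2", "n_teeth", "AvgTA", "nteeth_P", "nteeth_Pi")
}

measurement_columns <- function() {
  c("species", "sample_id", "leaf_id", "blade_area_cm2", "perimeter_cm",
    "internal_perimeter_cm", "teeth_removed_area_cm2", "major_axis_cm",
    "minor_axis_cm", "n_primary_teeth", "n_secondary_teeth")
}

#' Check per-leaf measurement records against their geometric invariants
#'
#' Validates the raw measurement schema: positive areas and perimeters,
#' internal perimeter no longer than the full perimeter, teeth-removed area
#' no larger than the blade area, major axis at least the minor axis,
#' nonnegative integer tooth counts, and consistency of untoothed leaves
#' (no teeth implies `Pi == P` and `teeth_removed_area == A`). The
#' isoperimetric bound `P^2 >= 4*pi*A` (shape factor at most 1) is checked
#' with a small relative tolerance for measurement slop.
#'
#' @param m Data frame with the columns of [measurement_columns()].
#' @param tol Relative tolerance applied to inequality checks.
#' @return A data frame with columns `row`, `field`, `message`; zero rows
#'   when all records are valid.
#' @export
validate_measurements <- function(m, tol = 1e-6) {
  missing <- setdiff(measurement_columns(), names(m))
  if (length(missing))
    stop("measurement table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  problems <- list()
  bad <- function(rows, field, msg) {
    if (any(rows)) problems[[length(problems) + 1L]] <<-
        data.frame(row = which(rows), field = field, message = msg)
  }
  A <- m$blade_area_cm2; P <- m$perimeter_cm; Pi <- m$internal_perimeter_cm
  ta_rm <- m$teeth_removed_area_cm2
  maj <- m$major_axis_cm; min_ <- m$minor_axis_cm
  n1 <- m$n_primary_teeth; n2 <- m$n_secondary_teeth
  bad(!is.finite(A) | A <= 0, "blade_area_cm2", "must be > 0")
  bad(!is.finite(P) | P <= 0, "perimeter_cm", "must be > 0")
  bad(!is.finite(Pi) | Pi <= 0, "internal_perimeter_cm", "must be > 0")
  bad(is.finite(Pi) & is.finite(P) & Pi > P * (1 + tol),
      "internal_perimeter_cm", "exceeds perimeter")
  bad(is.finite(ta_rm) & is.finite(A) & ta_rm > A * (1 + tol),
      "teeth_removed_area_cm2", "exceeds blade area")
  bad(!is.finite(maj) | maj <= 0, "major_axis_cm", "must be > 0")
  bad(!is.finite(min_) | min_ <= 0, "minor_axis_cm", "must be > 0")
  bad(is.finite(maj) & is.finite(min_) & min_ > maj * (1 + tol),
      "minor_axis_cm", "exceeds major axis")
  bad(!is.finite(n1) | n1 < 0 | n1 != round(n1), "n_primary_teeth",
      "must be a nonnegative integer")
  bad(!is.finite(n2) | n2 < 0 | n2 != round(n2), "n_secondary_teeth",
      "must be a nonnegative integer")
  bad(is.finite(P) & is.finite(A) & P^2 < 4 * pi * A * (1 - tol),
      "perimeter_cm", "violates isoperimetric bound (shape factor > 1)")
  untoothed <- is.finite(n1) & is.finite(n2) & n1 + n2 == 0
  bad(untoothed & abs(Pi - P) > tol * P, "internal_perimeter_cm",
      "untoothed leaf must have Pi == P")
  bad(untoothed & abs(ta_rm - A) > tol * A, "teeth_removed_area_cm2",
      "untoothed leaf must have teeth_removed_area == A")
  if (!length(problems))
    return(data.frame(row = integer(), field = character(),
                      message = character()))
  out <- do.call(rbind, problems)
  out[order(out$row), , drop = FALSE]
}

#' Derive the twenty physiognomy traits from raw leaf measurements
#'
#' Computes, per leaf: `Pratio = P/Pi`, `Comp = P^2/A`,
#' `ShapFact = 4*pi*A/P^2`, `FerDiam = 2*sqrt(A/pi)`,
#' `FerDiamRatio = FerDiam/MajLen`, tooth area `TA = A - teeth_removed_area`
#' and its ratios, tooth counts and densities. `AvgTA` is defined as 0 for
#' leaves without primary teeth (untoothed leaves carry a tooth area of
#' zero). A slightly negative `TA` arising from measurement slop is clamped
#' to 0 with a warning rather than rejected.
#'
#' @param m Data frame of per-leaf measurements (see
#'   [measurement_columns()]); lengths in cm, areas in cm^2.
#' @return A data frame with `species`, `sample_id`, `leaf_id` and the 20
#'   trait columns of [trait_names()].
#' @examples
#' # a unit circle without teeth: shape factor exactly 1
#' m <- data.frame(species = "sp", sample_id = "s1", leaf_id = "l1",
#'   blade_area_cm2 = pi, perimeter_cm = 2 * pi,
#'   internal_perimeter_cm = 2 * pi, teeth_removed_area_cm2 = pi,
#'   major_axis_cm = 2, minor_axis_cm = 2,
#'   n_primary_teeth = 0, n_secondary_teeth = 0)
#' derive_traits(m)$ShapFact
#' @export
derive_traits <- function(m) {
  problems <- validate_measurements(m)
  if (nrow(problems))
    stop("invalid measurements (first: row ", problems$row[1], ", field ",
         problems$field[1], ": ", problems$message[1], ")", call. = FALSE)
  A <- m$blade_area_cm2; P <- m$perimeter_cm; Pi <- m$internal_perimeter_cm
  TA <- A - m$teeth_removed_area_cm2
  if (any(TA < 0)) {
    warning(sum(TA < 0), " leaf/leaves with teeth_removed_area > blade area",
            " within tolerance; tooth area clamped to 0")
    TA <- pmax(TA, 0)
  }
  n1 <- m$n_primary_teeth; n2 <- m$n_secondary_teeth
  out <- data.frame(
    species = m$species, sample_id = m$sample_id, leaf_id = m$leaf_id,
    A = A, P = P, Pi = Pi,
    Pratio = P / Pi,
    Comp = P^2 / A,
    ShapFact = 4 * pi * A / P^2,
    MajLen = m$major_axis_cm, MinLen = m$minor_axis_cm,
    FerDiam = 2 * sqrt(A / pi),
    FerDiamRatio = 2 * sqrt(A / pi) / m$major_axis_cm,
    TA = TA,
    TABA = TA / A,
    TA_P = TA / P,
    TA_Pi = TA / Pi,
    teeth1 = n1, teeth2 = n2, n_teeth = n1 + n2,
    AvgTA = ifelse(n1 > 0, TA / pmax(n1, 1), 0),
    nteeth_P = (n1 + n2) / P,
    nteeth_Pi = (n1 + n2) / Pi,
    stringsAsFactors = FALSE
  )
  out
}

#' Aggregate per-leaf traits to a species trait table
#'
#' Pools all leaves of a species and takes the chosen statistic per trait.
#' The study design behind this package analyses species means, with minimum
#' and maximum runs as robustness checks.
#'
#' @param traits Per-leaf trait data frame from [derive_traits()].
#' @param stat One of `"mean"`, `"min"`, `"max"`.
#' @return A `species_trait_table`: data frame with a `species` column and
#'   the 20 trait columns, with attributes `stat` and `transform = "raw"`.
#' @export
aggregate_species <- function(traits, stat = c("mean", "min", "max")) {
  stat <- match.arg(stat)
  if (!nrow(traits)) stop("no trait records to aggregate", call. = FALSE)
  fun <- switch(stat, mean = mean, min = min, max = max)
  sp <- as.character(traits$species)
  cols <- trait_names()
  agg <- lapply(cols, function(cl) tapply(traits[[cl]], sp, fun))
  out <- data.frame(species = sort(unique(sp)), stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[cols[i]]] <- as.numeric(agg[[i]][out$species])
  if (anyNA(out[cols])) stop("missing cells after aggregation", call. = FALSE)
  structure(out, stat = stat, transform = "raw",
            class = c("species_trait_table", "data.frame"))
}

#' Ln(x + 1) transform of a species trait table
#'
#' Applies `log(x + 1)` to every trait cell to improve normality and
#' homogeneity before likelihood fitting. The transform is recorded in the
#' table's `transform` attribute; applying it twice is an error. Because the
#' transform is not scale-invariant, inputs must be in the cm/cm^2 units the
#' measurement schema declares.
#'
#' @param table A `species_trait_table` with `transform == "raw"`.
#' @return The transformed table, `transform == "ln1p"`.
#' @export
ln1p_transform <- function(table) {
  if (!inherits(table, "species_trait_table"))
    stop("'table' must come from aggregate_species()", call. = FALSE)
  if (identical(attr(table, "transform"), "ln1p"))
    stop("table is already Ln(x+1)-transformed", call. = FALSE)
  cols <- trait_names()
  vals <- as.matrix(table[cols])
  if (any(vals < 0))
    stop("negative trait values cannot be Ln(x+1)-transformed", call. = FALSE)
  table[cols] <- log1p(vals)
  attr(table, "transform") <- "ln1p"
  table
}

#' Pearson correlation matrix of the species trait table
#'
#' @param table A `species_trait_table` with at least 3 species.
#' @return A 20 x 20 symmetric correlation matrix in [trait_names()] order.
#'   Constant trait columns yield `NA` rows/columns and a warning naming
#'   them.
#' @export
trait_correlations <- function(table) {
  if (!inherits(table, "species_trait_table"))
    stop("'table' must come from aggregate_species()", call. = FALSE)
  if (nrow(table) < 3)
    stop("at least 3 species are required", call. = FALSE)
  vals <- as.matrix(table[trait_names()])
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    warning("constant trait column(s), correlation undefined: ",
            paste(colnames(vals)[sds == 0], collapse = ", "))
  suppressWarnings(cor(vals, method = "pearson"))
}

#' Read a per-leaf measurement CSV
#'
#' One row per leaf with the columns of [measurement_columns()]; the column
#' names declare the units (cm, cm^2). Lines starting with `#` (such as the
#' parameter stamp written by [write_measurements()]) are skipped.
#'
#' @param file CSV path.
#' @return Data frame of measurements.
#' @export
read_measurements <- function(file) {
  m <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(measurement_columns(), names(m))
  if (length(missing))
    stop("measurement CSV lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m
}

#' Write a per-leaf measurement CSV
#'
#' @param m Measurement data frame.
#' @param file Output path.
#' @param comment Optional provenance line (seed, parameters) written as a
#'   leading `#` comment.
#' @export
write_measurements <- function(m, file, comment = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(m, con, row.names = FALSE)
  invisible(file)
}
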