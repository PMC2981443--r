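#' Read a specimen morphometrics CSV
#'
#' Expected header: `taxon`, `element`, `a_out_mm`, `b_out_mm`, either
#' `a_in_mm` + `b_in_mm` or `cortical_thickness_mm`, `length_mm`,
#' `mass_kg`. `mass_kg` may hold a semicolon-separated list of candidate
#' body masses. Every row is validated through [bone_section()]; errors
#' name the offending row and column.
#'
#' @param path Path to a comma-separated, UTF-8, headered CSV.
#' @return A data frame with one row per specimen, inner radii resolved,
#'   and a `mass_kg` character column of semicolon-joined candidates.
#' @export
read_specimen_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty specimen file: ", path)
  required <- c("taxon", "element", "a_out_mm", "b_out_mm", "length_mm",
                "mass_kg")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  has_inner <- all(c("a_in_mm", "b_in_mm") %in% names(df))
  has_thick <- "cortical_thickness_mm" %in% names(df)
  if (!has_inner && !has_thick)
    stop("need either a_in_mm/b_in_mm or cortical_thickness_mm columns")
  for (i in seq_len(nrow(df))) {
    masses <- suppressWarnings(
      as.numeric(strsplit(as.character(df$mass_kg[i]), ";")[[1]]))
    if (any(is.na(masses)))
      stop(sprintf("row %d, column mass_kg: non-numeric value", i))
    sec <- tryCatch({
      if (has_inner)
        bone_section(df$taxon[i], df$element[i], df$a_out_mm[i],
                     df$b_out_mm[i], df$a_in_mm[i], df$b_in_mm[i],
                     length = df$length_mm[i], body_mass_candidates = masses)
      else
        bone_section(df$taxon[i], df$element[i], df$a_out_mm[i],
                     df$b_out_mm[i],
                     cortical_thickness = df$cortical_thickness_mm[i],
                     length = df$length_mm[i], body_mass_candidates = masses)
    }, error = function(e)
      stop(sprintf("row %d: %s", i, conditionMessage(e)), call. = FALSE))
    df$a_in_mm[i] <- sec$a_in
    df$b_in_mm[i] <- sec$b_in
    df$mass_kg[i] <- paste(masses, collapse = ";")
  }
  df
}

#' Read a planform CSV
#'
#' Expected header: `label`, `span_m`, `mass_kg`, `area_m2`.
#'
#' @param path Path to the CSV.
#' @return A validated data frame (positive spans, masses, areas).
#' @export
read_planform_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("label", "span_m", "mass_kg", "area_m2")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("span_m", "mass_kg", "area_m2")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad))
      stop(sprintf("row %d, column %s: non-positive or non-numeric value",
                   bad[1], col))
  }
  df
}

#' Read an ecomorphospace hull vertex CSV
#'
#' Expected header: `x`, `y` (hull vertices in order).
#'
#' @param path Path to the CSV.
#' @return A two-column numeric matrix.
#' @export
read_hull_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df))) stop("hull CSV needs x,y columns")
  as.matrix(df[, c("x", "y")])
}

#' Read a YAML run configuration
#'
#' Recognised top-level keys: `material`, `glide`, `burst`,
#' `span_mass_regression` — each a mapping whose entries override the
#' corresponding constructor defaults (unknown keys are an error, to
#' catch typos in parameter names).
#'
#' @param path Path to a YAML file.
#' @return A list with `material` ([material_params()]), `glide`
#'   ([glide_polar_params()]), `burst` ([burst_model()] or `NULL`), and
#'   `span_mass_regression` ([span_mass_regression()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  build <- function(fn, overrides, required_ok = TRUE) {
    overrides <- overrides %||% list()
    known <- names(formals(fn))
    unknown <- setdiff(names(overrides), known)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(fn, overrides)
  }
  list(
    material = build(material_params, cfg$material),
    glide = build(glide_polar_params, cfg$glide),
    burst = if (is.null(cfg$burst)) NULL else build(burst_model, cfg$burst),
    span_mass_regression = build(span_mass_regression,
                                 cfg$span_mass_regression))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis report
#'
#' CSV reports get deterministic column order (as given) and, for each
#' numeric column, a companion `<name>_printed` column rounded half-up to
#' `digits` decimals for comparison against published tables. JSON
#' reports serialise at full precision and round-trip through
#' [read_report()].
#'
#' @param results A non-empty data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param digits Decimals for the printed-precision companion columns.
#' @return Invisibly, the path.
#' @export
write_report <- function(results, path, format = c("csv", "json"),
                         digits = 2) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("results must be a non-empty data frame")
  if (format == "csv") {
    out <- results
    for (col in names(results)) {
      if (is.numeric(results[[col]]))
        out[[paste0(col, "_printed")]] <- round_half_up(results[[col]], digits)
    }
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return A data frame.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path)
}

#' Packaged transcription of the published giant-pterosaur strength table
#'
#' Eight rows: length-corrected polar section modulus, wingspan, body
#' mass, relative failure force, avian expectation and observed/expected
#' ratio for azhdarchid humeri, a femur and a cervical vertebra (the
#' cervical has no avian expectation — birds have no comparable tubular
#' neck element). The three Quetzalcoatlus northropi rows evaluate the
#' same bone at three candidate body masses.
#'
#' @return A data frame with columns `id`, `taxon`, `element`,
#'   `section_modulus_length_corrected`, `wingspan_m`, `mass_kg`, `rff`,
#'   `avian_expectation`, `ratio`.
#' @export
azhdarchid_strength_table <- function() {
  utils::read.csv(system.file("extdata", "table2.csv", package = "pterosoar"),
                  stringsAsFactors = FALSE)
}

#' Packaged transcription of the published wing-attribute table
#'
#' Planform records (span, mass, wing area) with the published derived
#' columns (weight, aspect ratio, wing loading) for giant pterosaur
#' reconstructions and procellariiform seabirds.
#'
#' @return A data frame with columns `taxon`, `common_name`, `group`,
#'   `span_m`, `mass_kg`, `area_m2`, `weight_N`, `aspect_ratio`,
#'   `wing_loading`, `reference`.
#' @export
wing_attribute_table <- function() {
  utils::read.csv(system.file("extdata", "table1.csv", package = "pterosoar"),
                  stringsAsFactors = FALSE)
}

#' Avian scaling models calibrated to the packaged strength table
#'
#' Fits [fit_avian_scaling()] to the (mass, avian expectation) pairs of
#' [azhdarchid_strength_table()]; reproduces the table's expectation
#' column to within 2%.
#'
#' @return Named list of [avian_scaling_model()] objects (`humerus`,
#'   `femur`).
#' @export
packaged_avian_scaling <- function() {
  t2 <- azhdarchid_strength_table()
  ok <- !is.na(t2$avian_expectation)
  fit_avian_scaling(t2$mass_kg[ok], t2$avian_expectation[ok], t2$element[ok])
}

#' Bone-strength report for a specimen table
#'
#' Runs the full elliptical-beam pipeline over a specimen table (one
#' output row per body-mass candidate): section properties, cantilever
#' failure force, relative failure force, avian expectation and
#' observed/expected ratio.
#'
#' @param specimens A data frame from [read_specimen_csv()] or
#'   [generate_bone_dataset()].
#' @param material A [material_params()].
#' @param models Named list of [avian_scaling_model()] per element
#'   (elements without a model get `NA` expectations).
#' @return A data frame mirroring the published strength-table columns.
#' @export
bone_strength_report <- function(specimens, material = material_params(),
                                 models = packaged_avian_scaling()) {
  rows <- list()
  for (i in seq_len(nrow(specimens))) {
    masses <- as.numeric(strsplit(as.character(specimens$mass_kg[i]),
                                  ";")[[1]])
    sec <- bone_section(specimens$taxon[i], specimens$element[i],
                        specimens$a_out_mm[i], specimens$b_out_mm[i],
                        specimens$a_in_mm[i], specimens$b_in_mm[i],
                        length = specimens$length_mm[i],
                        body_mass_candidates = masses)
    props <- section_properties(sec)
    model <- models[[sec$element]]
    for (m in masses) {
      a <- assess_failure(sec, m, material, model)
      rows[[length(rows) + 1]] <- data.frame(
        taxon = sec$taxon, element = sec$element,
        Zp_per_length = props$Zp_per_length,
        wingspan_m = if (is.null(sec$wingspan)) NA_real_ else sec$wingspan,
        mass_kg = m,
        failure_force_N = a$failure_force,
        rff = a$rff,
        avian_expectation = a$avian_expectation,
        ratio = a$ratio_observed_expected,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
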