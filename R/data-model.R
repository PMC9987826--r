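# Domain types, validation and delimited-text IO for the survey data.

SNAG_CATEGORIES <- c("<=5", "6-15", "16-30", "31-50", "51-100", ">100")
SNAG_VALUES <- c(1, 6, 16, 31, 51, 101)
SNAG_CLASSES <- c("small", "medium", "large")  # 10-30, 30-60, >60 cm dbh

#' Relative snag-density index from categorical field counts
#'
#' Snag counts within 50 m of a survey point are recorded in the field as
#' one of six abundance categories per diameter size class (10-30, 30-60,
#' >60 cm dbh). Each category maps to a numerical quantity
#' (`<=5` -> 1, `6-15` -> 6, `16-30` -> 16, `31-50` -> 31, `51-100` -> 51,
#' `>100` -> 101) and the index is the sum of the mapped values over the
#' three size classes.
#'
#' @param category_counts Character vector of length 3, one category label
#'   per size class, drawn from
#'   `c("<=5", "6-15", "16-30", "31-50", "51-100", ">100")`.
#' @return The integer snag-density index.
#' @examples
#' snag_index(c("<=5", "<=5", "<=5"))      # 3
#' snag_index(c("6-15", "16-30", "31-50")) # 53
#' @export
snag_index <- function(category_counts) {
  if (length(category_counts) != 3L)
    stop("expected one category per size class (3 values)")
  idx <- match(category_counts, SNAG_CATEGORIES)
  if (anyNA(idx))
    stop("unknown snag category label(s): ",
         paste(unique(category_counts[is.na(idx)]), collapse = ", "))
  sum(SNAG_VALUES[idx])
}

#' Construct a multi-fire study design
#'
#' Describes the fire-level layout: year burned, number of survey points,
#' and the calendar years in which woodpecker surveys were conducted. The
#' reference year (the final survey year, when beetle surveys occur) maps to
#' model year `t = T`; the modelled series spans from the earliest fire's
#' first post-fire year to the reference year.
#'
#' @param fires Data frame with columns `fire_id`, `year_burned`, `n_points`.
#' @param survey_years Named list (names = fire ids) of integer vectors of
#'   calendar survey years.
#' @param reference_year Calendar year mapped to `t = T`; every fire must be
#'   surveyed in this year.
#' @return An object of class `mtocc_design`.
#' @export
study_design <- function(fires, survey_years, reference_year = 2018L) {
  fires <- as.data.frame(fires)
  stopifnot(all(c("fire_id", "year_burned", "n_points") %in% names(fires)))
  fires$fire_id <- as.character(fires$fire_id)
  fires$year_burned <- as.integer(fires$year_burned)
  fires$n_points <- as.integer(fires$n_points)
  if (anyDuplicated(fires$fire_id)) stop("duplicate fire_id in design")
  if (!setequal(names(survey_years), fires$fire_id))
    stop("survey_years names must match fire ids")
  survey_years <- lapply(survey_years[fires$fire_id],
                         function(y) sort(as.integer(y)))
  reference_year <- as.integer(reference_year)
  for (i in seq_len(nrow(fires))) {
    fid <- fires$fire_id[i]
    sy <- survey_years[[fid]]
    if (length(sy) == 0L) stop("fire ", fid, " has no survey years")
    if (fires$year_burned[i] >= min(sy))
      stop("fire ", fid, " burned in ", fires$year_burned[i],
           ", not before its first survey year ", min(sy))
    if (!reference_year %in% sy)
      stop("fire ", fid, " is not surveyed in the reference year ",
           reference_year)
  }
  if (any(fires$n_points < 1L)) stop("n_points must be >= 1")
  structure(list(fires = fires, survey_years = survey_years,
                 reference_year = reference_year),
            class = "mtocc_design")
}

# Number of modelled years: earliest fire's first post-fire year is t = 1,
# the reference year is t = T.
design_T <- function(design) {
  design$reference_year - min(design$fires$year_burned)
}

# Calendar year of model year t = 0 (so t = year - year0).
design_year0 <- function(design) {
  design$reference_year - design_T(design)
}

#' @export
print.mtocc_design <- function(x, ...) {
  cat("Study design:", nrow(x$fires), "fires,", sum(x$fires$n_points),
      "points, reference year", x$reference_year,
      sprintf("(T = %d model years)\n", design_T(x)))
  invisible(x)
}

#' Assemble and validate a survey dataset
#'
#' Bundles the study design, woodpecker detection records, final-year
#' beetle surveys and point covariates, and checks every structural
#' invariant (see Details). Point-years with no surveys simply carry no
#' detection rows; they are treated as missing data, not as non-detections.
#'
#' @details Validated invariants include: every detection and beetle record
#' references a known point; detection years belong to the fire's survey
#' years; within a point-year, intervals are ordered, at most 3 passive and
#' 3 broadcast, and intervals after the first detection are censored
#' (removal design) and carry no detection value; beetle activity satisfies
#' `0 <= activity <= num_trees * 8` with `num_trees` in 1..6; pine
#' proportion lies in \[0, 1\]; snag categories are valid labels.
#'
#' @param design An `mtocc_design`.
#' @param detections Data frame: `fire_id`, `point_id`, `year`, `interval`,
#'   `type` (passive = 0, broadcast = 1), `detected` (0/1, `NA` when
#'   censored), `censored` (0/1).
#' @param beetle Data frame: `point_id`, `num_trees`, `activity`.
#' @param covariates Data frame: `point_id`, `fire_id`, `elevation_m`,
#'   `latitude`, `pine_prop`, plus snag category columns named
#'   `snag_<class>_<year>` for class in small/medium/large.
#' @return An object of class `mtocc_data`.
#' @export
survey_dataset <- function(design, detections, beetle, covariates) {
  x <- structure(list(design = design,
                      detections = as.data.frame(detections),
                      beetle = as.data.frame(beetle),
                      covariates = as.data.frame(covariates)),
                 class = "mtocc_data")
  validate_dataset(x)
  x
}

validate_dataset <- function(x) {
  stopifnot(inherits(x, "mtocc_data"))
  d <- x$detections; b <- x$beetle; cv <- x$covariates; des <- x$design
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, " is missing required column(s): ",
           paste(miss, collapse = ", "))
  }
  need(d, c("fire_id", "point_id", "year", "interval", "type", "detected",
            "censored"), "detections")
  need(b, c("point_id", "num_trees", "activity"), "beetle")
  need(cv, c("point_id", "fire_id", "elevation_m", "latitude", "pine_prop"),
       "covariates")

  if (anyDuplicated(cv$point_id)) stop("duplicate point_id in covariates")
  if (!all(cv$fire_id %in% des$fires$fire_id))
    stop("covariates reference unknown fire(s): ",
         paste(setdiff(cv$fire_id, des$fires$fire_id), collapse = ", "))
  if (any(cv$pine_prop < 0 | cv$pine_prop > 1, na.rm = TRUE))
    stop("pine_prop outside [0, 1] for point(s): ",
         paste(cv$point_id[which(cv$pine_prop < 0 | cv$pine_prop > 1)],
               collapse = ", "))
  # snag category labels
  for (col in grep("^snag_(small|medium|large)_\\d{4}$", names(cv),
                   value = TRUE)) {
    vals <- cv[[col]]
    bad <- !is.na(vals) & nzchar(vals) & !(vals %in% SNAG_CATEGORIES)
    if (any(bad))
      stop("invalid snag category in ", col, ": ",
           paste(unique(vals[bad]), collapse = ", "))
  }

  if (nrow(d)) {
    if (!all(d$point_id %in% cv$point_id))
      stop("detections reference unknown point(s): ",
           paste(unique(setdiff(d$point_id, cv$point_id)), collapse = ", "))
    if (!all(d$type %in% c(0, 1))) stop("detection type must be 0 or 1")
    if (!all(d$censored %in% c(0, 1))) stop("censored must be 0 or 1")
    obs <- d$censored == 0
    if (any(!d$detected[obs] %in% c(0, 1)))
      stop("detected must be 0/1 on non-censored intervals")
    if (any(!is.na(d$detected[!obs])))
      stop("censored intervals must carry no detected value")
    for (i in seq_len(nrow(d))) {
      fid <- as.character(d$fire_id[i])
      if (!d$year[i] %in% des$survey_years[[fid]])
        stop("detection row ", i, " (point ", d$point_id[i], ", year ",
             d$year[i], ") is outside fire ", fid, "'s survey years")
    }
    sp <- split(seq_len(nrow(d)), paste(d$point_id, d$year))
    for (ix in sp) {
      dd <- d[ix, ]
      if (anyDuplicated(dd$interval))
        stop("duplicate interval index for point ", dd$point_id[1],
             " year ", dd$year[1])
      if (sum(dd$type == 0) > 3L || sum(dd$type == 1) > 3L)
        stop("more than 3 intervals of one survey type for point ",
             dd$point_id[1], " year ", dd$year[1])
      dd <- dd[order(dd$interval), ]
      det_at <- which(!is.na(dd$detected) & dd$detected == 1)
      if (length(det_at)) {
        first <- min(det_at)
        if (first < nrow(dd) && any(dd$censored[(first + 1):nrow(dd)] != 1))
          stop("intervals after the first detection must be censored ",
               "(point ", dd$point_id[1], " year ", dd$year[1], ")")
      }
    }
  }

  if (nrow(b)) {
    if (!all(b$point_id %in% cv$point_id))
      stop("beetle surveys reference unknown point(s): ",
           paste(unique(setdiff(b$point_id, cv$point_id)), collapse = ", "))
    if (anyDuplicated(b$point_id)) stop("duplicate beetle survey per point")
    if (any(b$num_trees < 1 | b$num_trees > 6))
      stop("num_trees must lie in 1..6; offending point(s): ",
           paste(b$point_id[b$num_trees < 1 | b$num_trees > 6],
                 collapse = ", "))
    bad <- b$activity < 0 | b$activity > b$num_trees * 8
    if (any(bad))
      stop("activity outside [0, num_trees * 8] for point(s): ",
           paste(b$point_id[bad], collapse = ", "))
  }
  invisible(x)
}

#' @export
print.mtocc_data <- function(x, ...) {
  print(x$design)
  cat("  detections:", nrow(x$detections), "interval records;",
      "beetle surveys:", nrow(x$beetle), "points\n")
  if (!is.null(x$scaling)) cat("  covariates standardized\n")
  invisible(x)
}

# IO -------------------------------------------------------------------------

#' Read a survey dataset from delimited text
#'
#' Reads the four comma-separated files of the documented schema (header
#' row, UTF-8, empty fields for missing values) and returns a validated
#' dataset. `survey_years` in the design file is a semicolon-joined list.
#'
#' @param detections_path,beetle_path,covariates_path,design_path File paths.
#' @return A validated `mtocc_data` object.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(detections_path, beetle_path, covariates_path,
                         design_path) {
  des_df <- utils::read.csv(design_path, colClasses = c(fire_id = "character",
                                                        survey_years = "character"))
  need <- setdiff(c("fire_id", "year_burned", "n_points", "survey_years"),
                  names(des_df))
  if (length(need)) stop("design file missing column(s): ",
                         paste(need, collapse = ", "))
  sy <- lapply(strsplit(des_df$survey_years, ";", fixed = TRUE), as.integer)
  names(sy) <- des_df$fire_id
  ref <- max(unlist(sy))
  design <- study_design(des_df[c("fire_id", "year_burned", "n_points")],
                         sy, reference_year = ref)
  d <- utils::read.csv(detections_path,
                       colClasses = c(fire_id = "character",
                                      point_id = "character"))
  b <- utils::read.csv(beetle_path, colClasses = c(point_id = "character"))
  cv <- utils::read.csv(covariates_path,
                        colClasses = c(point_id = "character",
                                       fire_id = "character"))
  for (col in grep("^snag_", names(cv), value = TRUE)) {
    cv[[col]] <- as.character(cv[[col]])
    cv[[col]][!is.na(cv[[col]]) & !nzchar(cv[[col]])] <- NA_character_
  }
  survey_dataset(design, d, b, cv)
}

#' Write a survey dataset as delimited text
#'
#' Writes `detections.csv`, `beetle.csv`, `covariates.csv` and `design.csv`
#' into `dir` using the same schema [read_dataset()] consumes; the
#' round-trip reproduces the dataset (exactly for integer fields, to full
#' double precision for reals). Scaling constants are not serialized; they
#' are recomputed by [standardize_covariates()].
#'
#' @param dataset An `mtocc_data` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mtocc_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  des <- dataset$design
  des_df <- des$fires
  des_df$survey_years <- vapply(des$survey_years[des_df$fire_id],
                                paste, "", collapse = ";")
  paths <- file.path(dir, c("detections.csv", "beetle.csv",
                            "covariates.csv", "design.csv"))
  # doubles written at 17 significant digits so the round trip is exact
  wr2 <- function(df, path) {
    for (col in names(df)) {
      if (is.double(df[[col]]))
        df[[col]] <- vapply(df[[col]], function(v)
          if (is.na(v)) NA_character_ else sprintf("%.17g", v), "")
    }
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  wr2(dataset$detections, paths[1])
  wr2(dataset$beetle, paths[2])
  wr2(dataset$covariates, paths[3])
  wr2(des_df, paths[4])
  invisible(paths)
}

# Standardization -------------------------------------------------------------

zscore <- function(x, center, spread) (x - center) / spread

#' Standardize covariates for model fitting
#'
#' Centers and scales elevation, latitude, the snag-density index and years
#' since fire to z-scores; pine proportion (and hence beetle intensity)
#' stays on its natural \[0, 1\] scale. Means and standard deviations are
#' stored in `dataset$scaling` so predictions can be mapped back to natural
#' units. Snag and age are standardized over all in-window point-years
#' (from each point's first post-fire year to the reference year); the snag
#' index for years without a snag count is carried from the nearest
#' surveyed year (ties broken toward the earlier year).
#'
#' The operation is idempotent: it always recomputes from the raw columns,
#' and a raw column that is already mean-0, sd-1 is unchanged.
#'
#' @param dataset An `mtocc_data` object.
#' @return The dataset with `$scaling` (per-covariate center/spread) and
#'   `$std` (standardized design matrices) attached.
#' @export
standardize_covariates <- function(dataset) {
  stopifnot(inherits(dataset, "mtocc_data"))
  des <- dataset$design
  cv <- dataset$covariates
  Tn <- design_T(des)
  year0 <- design_year0(des)
  n <- nrow(cv)
  yb <- des$fires$year_burned[match(cv$fire_id, des$fires$fire_id)]
  entry_t <- yb + 1L - year0

  # raw age matrix (years since fire), NA outside the modelled window
  age <- matrix(NA_real_, n, Tn)
  for (t in seq_len(Tn)) {
    yr <- year0 + t
    age[, t] <- ifelse(t >= entry_t, yr - yb, NA_real_)
  }

  # raw snag index per point-year from category columns, then nearest-year
  # carry within the window
  snag_cols <- grep("^snag_(small|medium|large)_(\\d{4})$", names(cv),
                    value = TRUE)
  snag_years <- sort(unique(as.integer(sub("^snag_[a-z]+_", "", snag_cols))))
  snag_obs <- matrix(NA_real_, n, Tn)
  for (yr in snag_years) {
    t <- yr - year0
    if (t < 1L || t > Tn) next
    cols <- paste0("snag_", SNAG_CLASSES, "_", yr)
    if (!all(cols %in% names(cv))) next
    for (i in seq_len(n)) {
      cats <- as.character(unlist(cv[i, cols]))
      if (all(!is.na(cats) & nzchar(cats)))
        snag_obs[i, t] <- snag_index(cats)
    }
  }
  snag <- snag_obs
  for (i in seq_len(n)) {
    obs_t <- which(!is.na(snag_obs[i, ]))
    if (!length(obs_t)) next
    for (t in entry_t[i]:Tn) {
      if (is.na(snag[i, t])) {
        dist <- abs(obs_t - t)
        pick <- obs_t[dist == min(dist)]
        snag[i, t] <- snag_obs[i, min(pick)]  # tie -> earlier year
      }
    }
  }

  in_win <- !is.na(age)
  sc <- function(x, name) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(center = 0, spread = 1))  # covariate absent
    m <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("covariate '", name, "' has zero variance; cannot standardize")
    c(center = m, spread = s)
  }
  # age and snag may legitimately be constant (e.g. a single-year design);
  # they are then centered with unit spread and carry no information
  sc_loose <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(center = 0, spread = 1))
    s <- stats::sd(x)
    c(center = mean(x), spread = if (is.finite(s) && s > 0) s else 1)
  }
  scaling <- list(elevation = sc(cv$elevation_m, "elevation"),
                  latitude = sc(cv$latitude, "latitude"),
                  snag = sc_loose(snag[in_win]),
                  age = sc_loose(age[in_win]))
  # points with no snag count in any year sit at the covariate mean
  snag[in_win & is.na(snag)] <- scaling$snag["center"]
  std <- list(
    elev = zscore(cv$elevation_m, scaling$elevation["center"],
                  scaling$elevation["spread"]),
    lat = zscore(cv$latitude, scaling$latitude["center"],
                 scaling$latitude["spread"]),
    pine = cv$pine_prop,
    snag = zscore(snag, scaling$snag["center"], scaling$snag["spread"]),
    age = zscore(age, scaling$age["center"], scaling$age["spread"]),
    age_raw = age, snag_raw = snag, entry_t = entry_t,
    fire = match(cv$fire_id, des$fires$fire_id))
  dataset$scaling <- scaling
  dataset$std <- std
  dataset
}
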