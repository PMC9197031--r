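#' @keywords internal
"_PACKAGE"

# Continuous environmental predictors, in schema column order.
ENV_VARS <- c("alkalinity", "velocity", "nitrate", "total_phosphorus",
              "width", "depth")

# Units, for reports and axis labels.
ENV_UNITS <- c(alkalinity = "meq CaCO3 L-1", velocity = "m s-1",
               nitrate = "mg L-1", total_phosphorus = "ug L-1",
               width = "m", depth = "m")

# Closed vocabulary of dominant-substrate categories.
SUBSTRATE_LEVELS <- c("Silt, sand and gravel", "Sand", "Gravel and boulder",
                      "Gravel", "Silt and sand", "Sand and gravel",
                      "Rock and gravel")

# Variables for which zero is legal but negative is not; width and depth
# must be strictly positive when observed.
.POSITIVE_STRICT <- c("width", "depth")

#' Substrate category vocabulary
#'
#' The seven dominant-substrate categories recognised in site tables.  The
#' vocabulary is closed: any other label is rejected at load time (see
#' [read_site_table()] for synonym remapping).
#'
#' @return Character vector of the 7 category names.
#' @export
substrate_levels <- function() SUBSTRATE_LEVELS

#' Names of the continuous environmental predictors
#'
#' @return Character vector of the six continuous predictor columns of a
#'   site table, in schema order.
#' @export
env_variables <- function() ENV_VARS

#' Validate and classify a site table
#'
#' Checks a data frame against the site-table schema: a unique `site_id`
#' key, six non-negative continuous predictors (`width` and `depth`
#' strictly positive when observed) and a `substrate` factor drawn from the
#' closed 7-category vocabulary.  Missing cells are `NA`.
#'
#' @param df Data frame with columns `site_id`, the six continuous
#'   predictors and `substrate`.
#' @return The validated data frame with class `site_table`; `substrate` is
#'   a factor over [substrate_levels()].
#' @export
as_site_table <- function(df) {
  required <- c("site_id", ENV_VARS, "substrate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("site table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, required]
  df$site_id <- as.character(df$site_id)
  if (anyNA(df$site_id) || any(df$site_id == ""))
    stop("site_id must not be missing")
  if (anyDuplicated(df$site_id))
    stop("duplicate site_id: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  for (v in ENV_VARS) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    bad <- !is.na(df[[v]]) & is.na(x)
    if (any(bad))
      stop("non-numeric value in '", v, "': ",
           paste(utils::head(df[[v]][bad], 3), collapse = ", "))
    neg <- !is.na(x) & x < 0
    if (any(neg))
      stop("negative value in '", v, "' (", ENV_UNITS[[v]],
           " must be >= 0)")
    if (v %in% .POSITIVE_STRICT && any(!is.na(x) & x == 0))
      stop("'", v, "' must be strictly positive when observed")
    df[[v]] <- x
  }
  s <- df$substrate
  if (is.factor(s)) s <- as.character(s)
  s[!is.na(s) & s == ""] <- NA
  unknown <- setdiff(unique(s[!is.na(s)]), SUBSTRATE_LEVELS)
  if (length(unknown) > 0)
    stop("unknown substrate category '", unknown[1],
         "'; legal categories are: ",
         paste(SUBSTRATE_LEVELS, collapse = "; "))
  df$substrate <- factor(s, levels = SUBSTRATE_LEVELS)
  rownames(df) <- NULL
  class(df) <- c("site_table", "data.frame")
  df
}

#' Read a site table from CSV
#'
#' Reads `site_id`, the six continuous environmental predictors and the
#' categorical `substrate` column.  Both the empty string and `"NA"` encode
#' a missing cell.  Substrate labels outside the closed 7-category
#' vocabulary are rejected; `substrate_synonyms` remaps local spellings
#' onto the vocabulary before validation.
#'
#' @param path Path to a CSV file with header
#'   `site_id,alkalinity,velocity,nitrate,total_phosphorus,width,depth,substrate`.
#' @param substrate_synonyms Optional named character vector mapping
#'   synonym -> canonical category.
#' @return A `site_table` (see [as_site_table()]).
#' @export
read_site_table <- function(path, substrate_synonyms = NULL) {
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = c("", "NA"), check.names = FALSE)
  if (!is.null(substrate_synonyms) && "substrate" %in% names(df)) {
    hit <- df$substrate %in% names(substrate_synonyms)
    df$substrate[hit] <- substrate_synonyms[df$substrate[hit]]
  }
  as_site_table(df)
}

#' Write a site table to CSV
#'
#' Inverse of [read_site_table()]: missing cells are written as `"NA"`, so
#' a read/write round trip preserves the missingness mask exactly.
#'
#' @param x A `site_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate an occurrence table
#'
#' @param df Data frame with columns `site_id`, `species_id` and optionally
#'   a logical `aquatic` flag.
#' @return The validated data frame with class `occurrence_table`.
#' @export
as_occurrence_table <- function(df) {
  for (col in c("site_id", "species_id"))
    if (!col %in% names(df)) stop("occurrence table needs column '", col, "'")
  df <- as.data.frame(df)
  df$site_id <- as.character(df$site_id)
  df$species_id <- as.character(df$species_id)
  dup <- duplicated(df[, c("site_id", "species_id")])
  if (any(dup))
    stop("duplicate (site_id, species_id) record(s), e.g. (",
         df$site_id[dup][1], ", ", df$species_id[dup][1],
         "); multiple samples from a single site are not allowed")
  if ("aquatic" %in% names(df)) {
    a <- df$aquatic
    if (is.character(a)) a <- toupper(a) %in% c("TRUE", "T", "1", "YES")
    df$aquatic <- as.logical(a)
  }
  rownames(df) <- NULL
  class(df) <- c("occurrence_table", "data.frame")
  df
}

#' Read presence records from CSV
#'
#' @param path CSV with columns `site_id,species_id[,aquatic]`.
#' @return An `occurrence_table`; duplicated (site, species) pairs are an
#'   error.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = c("", "NA"), check.names = FALSE)
  as_occurrence_table(df)
}

#' Write an occurrence table to CSV
#' @param x An `occurrence_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Build a species-by-site presence matrix
#'
#' Converts presence records to a boolean species x sites matrix, dropping
#' species recorded at fewer than `min_sites` sites (rare species produce
#' non-representative co-occurrence clusters).  With `aquatic_only = TRUE`,
#' species flagged non-aquatic are removed before the occurrence filter.
#'
#' @param occ An `occurrence_table`.
#' @param min_sites Minimum number of sites a species must be recorded at
#'   to be retained (default 25; species with *fewer* records are dropped).
#' @param aquatic_only If `TRUE`, keep only records whose `aquatic` flag is
#'   `TRUE` (requires the `aquatic` column).
#' @return Logical matrix with species as rows and sites as columns (class
#'   `presence_matrix`), row and column names sorted for determinism.
#' @export
build_presence_matrix <- function(occ, min_sites = 25, aquatic_only = FALSE) {
  stopifnot(min_sites >= 1)
  df <- as.data.frame(occ)
  if (aquatic_only) {
    if (!"aquatic" %in% names(df))
      stop("aquatic_only = TRUE requires an 'aquatic' column")
    df <- df[!is.na(df$aquatic) & df$aquatic, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no species survive filter")
  counts <- table(df$species_id)
  keep <- names(counts)[counts >= min_sites]
  if (length(keep) == 0)
    stop("no species survive filter (min_sites = ", min_sites, ")")
  df <- df[df$species_id %in% keep, , drop = FALSE]
  species <- sort(unique(df$species_id))
  sites <- sort(unique(as.character(occ$site_id)))
  pm <- matrix(FALSE, nrow = length(species), ncol = length(sites),
               dimnames = list(species, sites))
  pm[cbind(match(df$species_id, species), match(df$site_id, sites))] <- TRUE
  structure(pm, class = c("presence_matrix", "matrix"),
            min_sites = min_sites)
}

#' Assemble the record-level modelling dataset
#'
#' One row per presence record: the site's seven environmental predictors
#' and the species' group label (the forest's target).  Predictors must be
#' complete -- impute first (see [impute_median_mode()] and
#' [impute_iterative_forest()]).
#'
#' @param pm A `presence_matrix` (filtered records).
#' @param sites A complete `site_table` covering every site in `pm`.
#' @param assignment Named integer vector, species_id -> group label in
#'   `1..k` (see [cut_dendrogram()]).
#' @return A `model_dataset`: list with `X` (data frame of predictors), `y`
#'   (integer labels), `species_id`, `site_id` and `k`.
#' @export
build_model_dataset <- function(pm, sites, assignment) {
  sp <- rownames(pm)
  if (!all(sp %in% names(assignment)))
    stop("assignment is missing species: ",
         paste(setdiff(sp, names(assignment)), collapse = ", "))
  idx <- which(pm, arr.ind = TRUE)
  rec_species <- rownames(pm)[idx[, 1]]
  rec_site <- colnames(pm)[idx[, 2]]
  m <- match(rec_site, sites$site_id)
  if (anyNA(m))
    stop("occurrence records reference unknown site(s): ",
         paste(utils::head(unique(rec_site[is.na(m)]), 3), collapse = ", "))
  X <- as.data.frame(sites)[m, c(ENV_VARS, "substrate"), drop = FALSE]
  rownames(X) <- NULL
  if (anyNA(X))
    stop("predictors contain missing cells; impute the site table first")
  y <- as.integer(assignment[rec_species])
  k <- max(y)
  if (!all(sort(unique(y)) == seq_len(k)))
    stop("group labels must cover 1..k")
  structure(list(X = X, y = y, species_id = rec_species,
                 site_id = rec_site, k = k),
            class = "model_dataset")
}

#' @export
print.model_dataset <- function(x, ...) {
  cat("model_dataset:", length(x$y), "records,", x$k, "groups,",
      ncol(x$X), "predictors\n")
  invisible(x)
}

# Sidecar metadata written next to pipeline CSV artifacts.
write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
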