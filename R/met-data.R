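#' Construct a multi-environment trial dataset
#'
#' Bundles plot-level records from a set of randomized complete block trials
#' (one trial per environment, an environment being a location-year
#' combination such as `"PU2018"`) into a validated `met_data` object, the
#' entry point for all model fitting in metstab.
#'
#' @param data A data frame with one row per plot, containing genotype,
#'   environment, replicate (block within environment) and yield columns.
#' @param gen,env,rep,yield Names of the four columns in `data`.
#'
#' @details Replicate labels are local to an environment (blocks are nested
#'   within trials); block "1" in one environment has no relationship to
#'   block "1" in another.  The dataset is *balanced* when every
#'   (genotype, environment, replicate) combination occurs exactly once,
#'   i.e. the record count equals g*e*r.  Model-fitting functions require a
#'   balanced dataset; use [subset_balanced()] to extract a balanced block
#'   from an incomplete one.
#'
#' @return An object of class `met_data`: a list with elements
#'   `data` (tibble with columns GEN, ENV, REP, YIELD), `g`, `e`, `r`,
#'   `balanced` (logical), `missing_cells` and `duplicated_cells`
#'   (tibbles of offending combinations, empty when balanced).
#'
#' @examples
#' d <- generate_met(g = 4, e = 3, r = 2, seed = 1)$data
#' d
#' @seealso [read_met_csv()], [cell_means()], [generate_met()]
#' @export
met_data <- function(data, gen = "GEN", env = "ENV", rep = "REP",
                     yield = "YIELD") {
  stopifnot(is.data.frame(data))
  cols <- c(gen = gen, env = env, rep = rep, yield = yield)
  missing_cols <- setdiff(unname(cols), names(data))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found in input: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::tibble(
    GEN   = as.character(data[[gen]]),
    ENV   = as.character(data[[env]]),
    REP   = as.character(data[[rep]]),
    YIELD = data[[yield]]
  )
  if (!is.numeric(df$YIELD)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$YIELD))) &
                   !is.na(df$YIELD))
    stop("non-numeric yield value", if (length(bad)) paste0(
      " at row ", bad[1L], " ('", df$YIELD[bad[1L]], "')"), call. = FALSE)
  }
  if (anyNA(df$YIELD)) {
    stop("missing yield value at row ", which(is.na(df$YIELD))[1L],
         call. = FALSE)
  }
  if (any(df$YIELD < 0)) {
    stop("negative yield at row ", which(df$YIELD < 0)[1L], call. = FALSE)
  }

  key <- paste(df$GEN, df$ENV, df$REP, sep = "\r")
  dup <- duplicated(key)
  dup_cells <- unique(df[dup, c("GEN", "ENV", "REP")])
  if (nrow(dup_cells) > 0L) {
    stop("duplicated (genotype, environment, replicate) record(s): ",
         paste(apply(dup_cells[seq_len(min(3L, nrow(dup_cells))), ], 1L,
                     paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }

  gens <- sort(unique(df$GEN))
  envs <- sort(unique(df$ENV))
  g <- length(gens); e <- length(envs)

  # blocks are nested in environments: completeness is judged per trial,
  # against that environment's own replicate labels
  rep_labels <- lapply(stats::setNames(envs, envs), function(ev)
    sort(unique(df$REP[df$ENV == ev])))
  miss_list <- lapply(envs, function(ev) {
    full <- expand.grid(GEN = gens, ENV = ev, REP = rep_labels[[ev]],
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    full_key <- paste(full$GEN, full$ENV, full$REP, sep = "\r")
    full[!(full_key %in% key), , drop = FALSE]
  })
  miss <- do.call(rbind, miss_list)
  r_per_env <- lengths(rep_labels)
  r <- max(r_per_env)
  balanced <- nrow(miss) == 0L && length(unique(r_per_env)) == 1L

  structure(
    list(
      data = df, g = g, e = e, r = r,
      genotypes = gens, environments = envs, replicates = rep_labels,
      balanced = balanced,
      missing_cells = tibble::as_tibble(miss)
    ),
    class = "met_data"
  )
}

#' @export
print.met_data <- function(x, ...) {
  cat(sprintf(
    "Multi-environment trial data: %d genotypes x %d environments x %d reps (%d plots)\n",
    x$g, x$e, x$r, nrow(x$data)))
  cat(if (x$balanced) "Balanced: yes\n" else
    sprintf("Balanced: NO (%d missing cell(s))\n", nrow(x$missing_cells)))
  print(utils::head(x$data, 4L))
  invisible(x)
}

#' Read a long-format trial CSV
#'
#' Reads plot-level MET data from a tidy CSV (one row per plot) and validates
#' it with [met_data()].  Default column names are `GEN`, `ENV`, `REP`,
#' `YIELD`; supply `col_map` to read files with other headers.
#'
#' @param path Path to the CSV file.
#' @param col_map Named character vector mapping the canonical names
#'   (`gen`, `env`, `rep`, `yield`) to the column names used in the file.
#' @return A [met_data] object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_met_csv(generate_met(3, 2, 3, seed = 1)$data, f)
#' read_met_csv(f)
#' @export
read_met_csv <- function(path,
                         col_map = c(gen = "GEN", env = "ENV",
                                     rep = "REP", yield = "YIELD")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  met_data(df, gen = col_map[["gen"]], env = col_map[["env"]],
           rep = col_map[["rep"]], yield = col_map[["yield"]])
}

#' Write a MET dataset back to a long-format CSV
#'
#' @param x A [met_data] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_met_csv <- function(x, path) {
  stopifnot(inherits(x, "met_data"))
  utils::write.csv(as.data.frame(x$data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Genotype-by-environment cell means
#'
#' Averages the r replicate plots of every (genotype, environment) cell,
#' producing the g x e two-way table on which AMMI and GGE operate.
#'
#' @param x A balanced [met_data] object.
#' @return A numeric matrix, rows = genotypes, columns = environments, in the
#'   sorted label order stored in `x`.
#' @export
cell_means <- function(x) {
  stopifnot(inherits(x, "met_data"))
  if (!x$balanced) {
    stop("dataset is not balanced; use subset_balanced() to extract a ",
         "complete genotype/environment block first", call. = FALSE)
  }
  tab <- tapply(x$data$YIELD, list(x$data$GEN, x$data$ENV), mean)
  tab[x$genotypes, x$environments, drop = FALSE]
}

#' Extract a balanced block from an incomplete MET
#'
#' Keeps the user-specified genotypes and environments (defaulting to all)
#' and then drops any genotype or environment that is not complete in the
#' retained block, mirroring how balanced datasets are carved out of a
#' multi-year breeding archive for AMMI/BLUP analysis.
#'
#' @param data A data frame of plot records (columns as in [met_data()]).
#' @param genotypes,environments Optional character vectors restricting the
#'   block before completion is enforced.
#' @param ... Passed to [met_data()] (column names).
#' @return A balanced [met_data] object.
#' @export
subset_balanced <- function(data, genotypes = NULL, environments = NULL, ...) {
  if (inherits(data, "met_data")) data <- data$data
  args <- list(...)
  gen <- if (!is.null(args$gen)) args$gen else "GEN"
  env <- if (!is.null(args$env)) args$env else "ENV"
  df <- data
  if (!is.null(genotypes))    df <- df[df[[gen]] %in% genotypes, , drop = FALSE]
  if (!is.null(environments)) df <- df[df[[env]] %in% environments, , drop = FALSE]
  # iteratively drop genotypes/environments with incomplete cells
  repeat {
    counts <- table(df[[gen]], df[[env]])
    r_full <- max(counts)
    bad_g <- rownames(counts)[apply(counts < r_full, 1L, any)]
    bad_e <- colnames(counts)[apply(counts < r_full, 2L, any)]
    if (length(bad_g) == 0L && length(bad_e) == 0L) break
    # drop whichever side removes fewer plots
    if (length(bad_e) <= length(bad_g) && length(bad_e) > 0L) {
      df <- df[!(df[[env]] %in% bad_e), , drop = FALSE]
    } else {
      df <- df[!(df[[gen]] %in% bad_g), , drop = FALSE]
    }
    if (nrow(df) == 0L) stop("no balanced block found", call. = FALSE)
  }
  met_data(df, ...)
}

#' Expand a dataset-specification string into environment identifiers
#'
#' Breeding reports describe trial sets compactly, e.g.
#' `"DA, FF, and PU (2012-2018), GE (2012, 2014-2018), GF (2012)"`: groups of
#' location codes followed by a parenthesised list of years and year ranges.
#' This parser expands such a description into the full, de-duplicated,
#' sorted list of environment identifiers (`<location><year>`).
#'
#' @param spec The specification string.  Year ranges may use `-` or the
#'   en dash; location groups may be separated by commas and/or "and".
#' @param known_locations Character vector of valid location codes; an
#'   unknown code is an error.
#' @return Character vector of environment identifiers, e.g. `"PU2018"`.
#' @examples
#' parse_dataset_spec("PU (2019-2021), GE and SJ (2019, 2021)")
#' @export
parse_dataset_spec <- function(spec,
                               known_locations = c("DA", "FF", "GE",
                                                   "GF", "PU", "SJ")) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- gsub("–", "-", spec)  # en dash
  m <- gregexpr("([^()]*)\\(([^)]*)\\)", spec)
  groups <- regmatches(spec, m)[[1L]]
  if (length(groups) == 0L) stop("no '(years)' group found in: ", spec,
                                 call. = FALSE)
  envs <- character(0)
  for (grp in groups) {
    locs_part  <- sub("\\(.*$", "", grp)
    years_part <- sub("^.*\\(([^)]*)\\).*$", "\\1", grp)
    locs <- regmatches(locs_part,
                       gregexpr("[A-Za-z]+", locs_part))[[1L]]
    locs <- toupper(setdiff(locs, c("and", "AND", "And")))
    if (length(locs) == 0L) stop("no location code before '(", years_part,
                                 ")'", call. = FALSE)
    unknown <- setdiff(locs, known_locations)
    if (length(unknown) > 0L) {
      stop("unknown location code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    years <- integer(0)
    for (tok in trimws(strsplit(years_part, ",")[[1L]])) {
      if (tok == "") next
      if (grepl("^\\d{4}\\s*-\\s*\\d{4}$", tok)) {
        bounds <- as.integer(regmatches(tok, gregexpr("\\d{4}", tok))[[1L]])
        years <- c(years, seq(bounds[1L], bounds[2L]))
      } else if (grepl("^\\d{4}$", tok)) {
        years <- c(years, as.integer(tok))
      } else {
        stop("cannot parse year token '", tok, "'", call. = FALSE)
      }
    }
    envs <- c(envs, as.vector(outer(locs, years, paste0)))
  }
  sort(unique(envs))
}
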