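#' @name gs_io
#' @title File formats
#'
#' @description
#' Plain-text interchange formats: pedigree as 4-column tab-separated text
#' (id, sire, dam, generation; 0 = unknown), G-matrices as dense
#' tab-separated squares with an id header row and column, phenotypes as
#' (id, phenotype, weight) TSV, genotypes as a PLINK-RAW-style dosage table,
#' and metrics as comma-separated CSV.  Ids are strings throughout.
NULL

#' Read and validate a pedigree file
#'
#' Expects tab-separated columns id, sire, dam, generation (header optional,
#' detected); 0 marks an unknown parent.  Records are topologically sorted
#' so parents precede offspring; cycles and duplicate ids are errors naming
#' the offending ids.
#'
#' @param path file path.
#' @return data.frame (id, sire, dam, generation) in parent-first order,
#'   with a logical \code{founder} column.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(raw) < 4)
    stop("read_pedigree: expected 4 tab-separated columns", call. = FALSE)
  if (suppressWarnings(is.na(as.numeric(raw[1, 4]))))
    raw <- raw[-1, , drop = FALSE]        # header row
  ped <- data.frame(id = raw[[1]], sire = raw[[2]], dam = raw[[3]],
                    generation = as.integer(raw[[4]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id))
    stop("read_pedigree: duplicate ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  n <- nrow(ped)
  sp <- match(ped$sire, ped$id); sp[ped$sire == "0"] <- NA
  dp <- match(ped$dam, ped$id); dp[ped$dam == "0"] <- NA
  # Kahn topological sort (parents before offspring); leftovers are cycles
  indeg_ok <- logical(n)
  order_out <- integer(0)
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(sp[i]) || indeg_ok[sp[i]]) && (is.na(dp[i]) || indeg_ok[dp[i]])
    }, logical(1))]
    if (length(ready) == 0) break
    indeg_ok[ready] <- TRUE
    order_out <- c(order_out, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining) > 0)
    stop("read_pedigree: pedigree cycle involving ids: ",
         paste(ped$id[remaining], collapse = ", "), call. = FALSE)
  ped <- ped[order_out, , drop = FALSE]
  rownames(ped) <- NULL
  ped$founder <- ped$sire == "0" & ped$dam == "0"
  ped
}

#' Write a pedigree file
#' @param ped pedigree data.frame (id, sire, dam, generation).
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped[, c("id", "sire", "dam", "generation")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a dense G-matrix file
#'
#' Tab-separated square matrix with an id header row and an id first column.
#'
#' @param path file path.
#' @param method method tag to attach ("vanraden" or "similarity").
#' @return a \code{gmatrix}.
#' @export
read_gmatrix <- function(path, method = "vanraden") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  G <- as.matrix(tab)
  if (nrow(G) != ncol(G))
    stop("read_gmatrix: matrix is not square", call. = FALSE)
  if (!identical(rownames(G), colnames(G)))
    stop("read_gmatrix: row/column id mismatch", call. = FALSE)
  new_gmatrix(G, method, rownames(G))
}

#' Write a G-matrix file
#' @param G a \code{gmatrix} (or square matrix with dimnames).
#' @param path output path.
#' @export
write_gmatrix <- function(G, path) {
  df <- data.frame(id = rownames(G), unclass(G), check.names = FALSE)
  colnames(df) <- c("id", colnames(G))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype file
#'
#' Tab-separated (id, phenotype, weight); the weight column is optional and
#' defaults to 1.
#'
#' @param path file path.
#' @return data.frame (id, phenotype, weight).
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("read_phenotypes: expected at least (id, phenotype) columns",
         call. = FALSE)
  names(tab)[1:2] <- c("id", "phenotype")
  tab$id <- as.character(tab$id)
  if (ncol(tab) < 3) tab$weight <- 1 else names(tab)[3] <- "weight"
  tab[, c("id", "phenotype", "weight")]
}

#' Write a phenotype file
#' @param df data.frame (id, phenotype, weight).
#' @param path output path.
#' @export
write_phenotypes <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage genotype table
#'
#' PLINK-RAW-style: header of marker names, first column of individual ids,
#' cells in \{0, 1, 2, NA\}.
#'
#' @param path file path.
#' @return numeric matrix with ids as row names.
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}

#' Write a dosage genotype table
#' @param X dosage matrix with id row names and marker column names.
#' @param path output path.
#' @export
write_genotypes <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  colnames(df) <- c("id", colnames(X))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the tidy metrics table
#'
#' Comma-separated, UTF-8, '.' decimal; columns replicate, generation,
#' strategy, mean_bv, mean_het, mean_f, mean_bias, ne, ne_over_n (plus any
#' extra columns present, e.g. ref_size).
#'
#' @param metrics metrics data.frame (or a \code{gs_scenario}).
#' @param path file path.
#' @export
write_metrics <- function(metrics, path) {
  if (inherits(metrics, "gs_scenario")) metrics <- metrics$metrics
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a run configuration file
#'
#' Single YAML file with optional sections \code{scheme}, \code{genome},
#' \code{trait}, \code{strategy}; recognized keys override the
#' \code{\link{scheme_config}} / \code{\link{genome_spec}} defaults.
#'
#' @param path YAML file path.
#' @return list with elements \code{config} (a \code{scheme_config}),
#'   \code{strategy} (a \code{strategy_config}) and \code{seed}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gn <- do.call(genome_spec, y$genome %||% list())
  sc <- y$scheme %||% list()
  tr <- y$trait %||% list()
  cfg <- do.call(scheme_config,
                 c(sc, list(genome = gn),
                   tr[intersect(names(tr), c("sigma2_g", "sigma2_e"))]))
  st <- y$strategy %||% list()
  ocp <- do.call(oc_params, st$oc %||% list())
  strat <- strategy_config(st$strategy %||% "random",
                           st$update_size %||% cfg$ref_update_size, ocp)
  list(config = cfg, strategy = strat, seed = y$seed %||% 1)
}
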