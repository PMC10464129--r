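# Readers/writers for the delimited-matrix and GMT gene-set formats the
# pipeline touches, plus bundle serialization. Matrix orientation is cell
# lines as rows and genes as columns everywhere; files stored the other way
# round are transposed at read time.

#' Read a delimited numeric matrix with labeled axes
#'
#' Expects one header row and one leading label column. Empty cells and `NA`
#' become missing values; duplicate labels and non-numeric payload are
#' rejected with an error naming the offender.
#'
#' @param path file path (TSV or CSV; separator auto-detected).
#' @param orientation `"lines_by_genes"` (rows are cell lines; the stored
#'   layout) or `"genes_by_lines"` (file is transposed relative to the
#'   in-memory convention).
#' @return numeric matrix, cell lines as rows.
#' @export
read_matrix <- function(path, orientation = c("lines_by_genes",
                                              "genes_by_lines")) {
  orientation <- match.arg(orientation)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = "auto",
                      na.strings = c("", "NA"), data.table = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(dt) < 2) stop("matrix file needs a label column plus data: ", path)
  labels <- as.character(dt[[1]])
  if (anyDuplicated(labels)) {
    stop("duplicated row labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  cols <- colnames(dt)[-1]
  if (anyDuplicated(cols)) {
    stop("duplicated column headers in ", path, ": ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "),
         call. = FALSE)
  }
  payload <- dt[, -1, drop = FALSE]
  bad <- vapply(payload, function(x) !is.numeric(x) && !all(is.na(x)),
                logical(1))
  if (any(bad)) {
    stop("non-numeric values in column(s) ",
         paste(cols[bad], collapse = ", "), " of ", path, call. = FALSE)
  }
  m <- as.matrix(payload)
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (orientation == "genes_by_lines") m <- t(m)
  m
}

#' Write a matrix as TSV with a label column
#'
#' Inverse of [read_matrix()]: round-trips finite values and missing masks
#' losslessly (full double precision).
#'
#' @param m matrix with dimnames (cell lines as rows).
#' @param path output path.
#' @param id_col name of the leading label column.
#' @export
write_matrix <- function(m, path, id_col = "cell_line") {
  assert_matrix_named(m, "m")
  # %.17g guarantees a bit-exact double round-trip
  chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  chr[is.na(m)] <- ""
  df <- data.table::as.data.table(chr, keep.rownames = id_col)
  data.table::fwrite(df, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read gene sets in GMT dialect
#'
#' Tab-separated lines: set name, description, then members. Duplicate
#' members are dropped with a warning; lines with fewer than three fields are
#' a parse error.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("GMT parse error at line ", i, " of ", path,
           ": expected name, description and at least one member",
           call. = FALSE)
    }
    members <- parts[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate members in gene set '", parts[1], "' deduplicated",
              call. = FALSE)
      members <- unique(members)
    }
    out[[parts[1]]] <- members
  }
  out
}

#' Write gene sets in GMT dialect
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sets)) {
    writeLines(paste(c(nm, description, sets[[nm]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a synthetic bundle to disk
#'
#' Gene-effect and reagent matrices become TSVs, control sets a GMT file, and
#' the ground truth a JSON file, alongside a manifest carrying the config
#' hash and seed.
#'
#' @param bundle a [synth_bundle()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(bundle$effects$A, file.path(dir, "gene_effect_A.tsv"))
  write_matrix(bundle$effects$B, file.path(dir, "gene_effect_B.tsv"))
  write_matrix(bundle$lfc$A$lfc, file.path(dir, "reagent_lfc_A.tsv"))
  write_matrix(bundle$lfc$B$lfc, file.path(dir, "reagent_lfc_B.tsv"))
  write_matrix(bundle$omics$expression, file.path(dir, "expression.tsv"))
  write_matrix(bundle$omics$features, file.path(dir, "omics_features.tsv"))
  data.table::fwrite(bundle$drugs$targets,
                     file.path(dir, "drug_targets.tsv"), sep = "\t")
  write_gene_sets(c(list(
    pan_truth = bundle$truth$genes[bundle$truth$archetype == "pan"]),
    bundle$truth$modules),
    file.path(dir, "truth_sets.gmt"))
  truth_json <- list(archetype = as.list(bundle$truth$archetype),
                     mechanism = as.list(bundle$truth$mechanism),
                     drug_targets = as.list(bundle$truth$drug_targets),
                     modules = bundle$truth$modules)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  manifest <- stage_manifest("synth", bundle$config, bundle$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

stage_manifest <- function(stage, config, seed, counts = list()) {
  list(stage = stage,
       config_hash = digest::digest(config, algo = "sha1"),
       seed = seed,
       counts = counts)
}
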