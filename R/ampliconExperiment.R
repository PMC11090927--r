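TAX_RANKS <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus", "Species")

#' Construct an AmpliconExperiment
#'
#' @param counts integer matrix of reads, ASVs as rows, samples as columns,
#'   with unique dimnames.
#' @param taxonomy optional data.frame of the seven ranks
#'   (Kingdom..Species), one row per ASV; rownames must cover the count
#'   table's ASVs. Missing ranks may be empty strings.
#' @param metadata data.frame with one row per sample (rownames or a
#'   `sample_id` column matching the count table's samples) and columns
#'   `reactor`, `date` (coercible to `Date`), optionally `temperature`.
#' @param ground_truth optional list of planted simulation parameters.
#' @return an [AmpliconExperiment-class]
#' @examples
#' cnt <- matrix(c(3L, 0L, 1L, 2L), 2, 2,
#'               dimnames = list(c("ASV1", "ASV2"), c("S1", "S2")))
#' md <- data.frame(reactor = c("AGS1", "CAS"),
#'                  date = as.Date(c("2020-06-15", "2020-06-15")),
#'                  row.names = c("S1", "S2"))
#' AmpliconExperiment(cnt, metadata = md)
#' @export
AmpliconExperiment <- function(counts, taxonomy = NULL, metadata,
                               ground_truth = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate ASV identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  storage.mode(counts) <- "integer"

  metadata <- as.data.frame(metadata)
  if ("sample_id" %in% colnames(metadata) &&
      !identical(rownames(metadata), metadata$sample_id)) {
    rownames(metadata) <- metadata$sample_id
  }
  missing <- setdiff(colnames(counts), rownames(metadata))
  if (length(missing))
    stop("metadata is missing sample(s): ", paste(missing, collapse = ", "))
  metadata <- metadata[colnames(counts), , drop = FALSE]
  if (!("date" %in% colnames(metadata)))
    stop("metadata must contain a 'date' column")
  metadata$date <- as.Date(metadata$date)
  if (any(is.na(metadata$date))) stop("metadata dates failed to parse")

  if (is.null(taxonomy)) {
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  } else {
    taxonomy <- as.data.frame(taxonomy)
    if ("asv_id" %in% colnames(taxonomy)) {
      rownames(taxonomy) <- taxonomy$asv_id
      taxonomy$asv_id <- NULL
    }
    if (anyDuplicated(rownames(taxonomy)))
      stop("duplicate ASV identifiers in taxonomy")
    miss <- setdiff(rownames(counts), rownames(taxonomy))
    if (length(miss))
      stop("taxonomy is missing ASV(s): ", paste(utils::head(miss, 5), collapse = ", "))
    rd <- S4Vectors::DataFrame(taxonomy[rownames(counts), , drop = FALSE])
  }

  meta <- if (is.null(ground_truth)) list() else list(ground_truth = ground_truth)
  new("AmpliconExperiment",
      SummarizedExperiment(assays = list(counts = counts),
                           rowData = rd,
                           colData = S4Vectors::DataFrame(metadata),
                           metadata = meta))
}

#' Sample metadata as a plain data.frame
#'
#' @param x an [AmpliconExperiment-class]
#' @return data.frame with `sample`, `reactor`, `date` and, when present,
#'   `temperature` columns
#' @export
sampleMetadata <- function(x) {
  cd <- as.data.frame(colData(x))
  out <- data.frame(sample = colnames(x), reactor = cd$reactor,
                    date = as.Date(cd$date), stringsAsFactors = FALSE)
  if ("temperature" %in% colnames(cd)) out$temperature <- cd$temperature
  out
}

#' Taxonomy table as a plain data.frame
#'
#' @param x an [AmpliconExperiment-class]
#' @return data.frame of taxonomic ranks, rownames = ASV ids
#' @export
taxonomyTable <- function(x) {
  as.data.frame(rowData(x))
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Read a dataset from tab-separated files
#'
#' Reads a count table (first column ASV ids, remaining columns one per
#' sample), and optionally taxonomy (columns `asv_id`, Kingdom..Species)
#' and sample metadata (`sample_id`, `reactor`, `date` in ISO-8601,
#' optionally `temperature`). Writing with [writeAmpliconTSV()] and
#' re-reading reproduces counts exactly, in the same order.
#'
#' @param counts path to the count TSV
#' @param taxonomy,metadata optional paths
#' @return an [AmpliconExperiment-class]; without metadata, samples are
#'   given reactor `"NA"` and an index date (suitable only for table ops).
#' @export
readAmpliconTSV <- function(counts, taxonomy = NULL, metadata = NULL) {
  df <- .read_tsv(counts)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("count table contains non-numeric entries")
  if (any(m < 0)) stop("count table contains negative entries")
  if (any(abs(m - round(m)) > 1e-8)) stop("count table contains non-integer entries")
  rownames(m) <- ids
  tax <- if (!is.null(taxonomy)) .read_tsv(taxonomy) else NULL
  md <- if (!is.null(metadata)) {
    x <- .read_tsv(metadata)
    rownames(x) <- x$sample_id
    x
  } else {
    data.frame(sample_id = colnames(m), reactor = "NA",
               date = as.Date("1970-01-01") + seq_len(ncol(m)),
               row.names = colnames(m))
  }
  AmpliconExperiment(m, taxonomy = tax, metadata = md)
}

#' Write a dataset as tab-separated files
#'
#' Writes `<prefix>_counts.tsv`, `<prefix>_taxonomy.tsv`,
#' `<prefix>_metadata.tsv` and, for synthetic data,
#' `<prefix>_ground_truth.json` into `dir`.
#'
#' @param x an [AmpliconExperiment-class]
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return invisibly, the named vector of written paths
#' @export
writeAmpliconTSV <- function(x, dir, prefix = "dataset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, paste0(prefix, "_counts.tsv")),
             taxonomy = file.path(dir, paste0(prefix, "_taxonomy.tsv")),
             metadata = file.path(dir, paste0(prefix, "_metadata.tsv")))
  cnt <- data.frame(asv_id = rownames(x), counts(x), check.names = FALSE)
  utils::write.table(cnt, paths["counts"], sep = "\t", quote = FALSE, row.names = FALSE)
  tax <- data.frame(asv_id = rownames(x), taxonomyTable(x), check.names = FALSE)
  utils::write.table(tax, paths["taxonomy"], sep = "\t", quote = FALSE, row.names = FALSE)
  md <- sampleMetadata(x)
  names(md)[names(md) == "sample"] <- "sample_id"
  md$date <- format(md$date, "%Y-%m-%d")
  utils::write.table(md, paths["metadata"], sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- groundTruth(x)
  if (!is.null(gt)) {
    gp <- file.path(dir, paste0(prefix, "_ground_truth.json"))
    slim <- gt[setdiff(names(gt), "latent")]  # the latent array stays in-memory
    slim$config <- unclass(slim$config)
    slim$config$start_date <- format(slim$config$start_date, "%Y-%m-%d")
    jsonlite::write_json(slim, gp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, ground_truth = gp)
  }
  invisible(paths)
}

#' Read a count table in BIOM format
#'
#' Thin wrapper around the `biomformat` package; observation metadata, when
#' present, is used as taxonomy.
#'
#' @param path a BIOM file
#' @param metadata optional sample metadata data.frame (as in
#'   [AmpliconExperiment()])
#' @return an [AmpliconExperiment-class]
#' @export
readAmpliconBiom <- function(path, metadata = NULL) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the 'biomformat' package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  tax <- NULL
  if (is.data.frame(om) && ncol(om) >= 1) {
    tax <- om
    colnames(tax) <- TAX_RANKS[seq_len(min(ncol(tax), 7L))]
  }
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = colnames(m), reactor = "NA",
                           date = as.Date("1970-01-01") + seq_len(ncol(m)),
                           row.names = colnames(m))
  }
  AmpliconExperiment(m, taxonomy = tax, metadata = metadata)
}

#' Write the count table in BIOM format
#'
#' @param x an [AmpliconExperiment-class]
#' @param path output file
#' @return invisibly, `path`
#' @export
writeAmpliconBiom <- function(x, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the 'biomformat' package is required to write BIOM files")
  b <- biomformat::make_biom(counts(x))
  biomformat::write_biom(b, path)
  invisible(path)
}
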