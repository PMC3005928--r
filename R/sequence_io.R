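#' Read a transcript set from FASTA
#'
#' Reads one species' transcripts, normalises sequences (uppercase, RNA `U`
#' mapped to `T`) and validates them: ids (first whitespace-delimited header
#' token) must be unique, sequences non-empty and restricted to the
#' `{A,C,G,T,N}` alphabet.
#'
#' @param path Path to a FASTA file.
#' @param species_label Character scalar attached to every record.
#' @return A [Biostrings::DNAStringSet] named by transcript id, with
#'   metadata columns `species` and `description`.
#' @export
read_transcripts <- function(path, species_label) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate transcript id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    k <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d of transcript '%s'",
                 substr(seqs[k], bad[k], bad[k]), bad[k], ids[k]),
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for transcript '", ids[which(nchar(seqs) == 0L)[1L]],
         "'", call. = FALSE)
  }
  transcript_set(seqs, ids = ids, species = species_label,
                 descriptions = desc)
}

#' Build a transcript set in memory
#'
#' @param sequences Character vector of DNA sequences over `{A,C,G,T,N}`
#'   (lowercase and `U` are normalised).
#' @param ids Unique transcript ids (defaults to `names(sequences)`).
#' @param species Species label, recycled across records.
#' @param descriptions Optional free-text descriptions.
#' @return A named [Biostrings::DNAStringSet] with `species` and
#'   `description` metadata columns.
#' @export
transcript_set <- function(sequences, ids = names(sequences),
                           species = "unknown", descriptions = "") {
  if (is.null(ids)) stop("transcript ids are required", call. = FALSE)
  stopifnot(length(ids) == length(sequences), !anyDuplicated(ids))
  seqs <- chartr("Uu", "Tt", toupper(as.character(sequences)))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  S4Vectors::mcols(dss) <- S4Vectors::DataFrame(
    species = rep_len(species, length(dss)),
    description = rep_len(descriptions, length(dss)))
  dss
}

#' Write a transcript set to FASTA
#'
#' @param transcripts A named [Biostrings::DNAStringSet] or named character
#'   vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  if (!methods::is(transcripts, "XStringSet")) {
    transcripts <- Biostrings::DNAStringSet(transcripts)
  }
  Biostrings::writeXStringSet(transcripts, path)
  invisible(path)
}

# normalise any supported transcript container to a named character vector
.tx_chars <- function(transcripts) {
  if (is.character(transcripts)) {
    if (length(transcripts) > 0L && is.null(names(transcripts))) {
      stop("transcript character vectors must be named by id", call. = FALSE)
    }
    return(transcripts)
  }
  setNames(as.character(transcripts), names(transcripts))
}

.probe_table_cols <- c("probe_id", "gene_id", "start", "length", "sequence",
                       "min_cross_distance", "nearest_nontarget",
                       "dist_to_3prime")

#' Write / read a probe table
#'
#' Tab-separated with a fixed header (`probe_id`, `gene_id`, `start`,
#' `length`, `sequence`, `min_cross_distance`, `nearest_nontarget`,
#' `dist_to_3prime`). Coordinates are 0-based; `start + length` never exceeds
#' the source transcript length. A missing `min_cross_distance` (empty field)
#' means the screening cap was exceeded, i.e. the probe is maximally
#' specific at the cap used. Round trips are lossless.
#'
#' @param rows Data frame of probe rows.
#' @param path File path.
#' @return `write_probe_table()` returns `path` invisibly;
#'   `read_probe_table()` returns the data frame.
#' @export
write_probe_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  miss <- setdiff(.probe_table_cols, names(rows))
  if (length(miss) > 0L) {
    stop("probe table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(nchar(rows$sequence) != rows$length |
                 rows$start < 0L | rows$dist_to_3prime < 0L |
                 (!is.na(rows$min_cross_distance) & rows$min_cross_distance < 0L))
  if (length(bad) > 0L) {
    stop("invalid probe row at position ", bad[1L], call. = FALSE)
  }
  write.table(rows[, .probe_table_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, colClasses = "character", na.strings = "",
                   check.names = FALSE)
  miss <- setdiff(.probe_table_cols, names(df))
  if (length(miss) > 0L) {
    stop("probe table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(probe_id = df$probe_id, gene_id = df$gene_id,
                    start = .parse_int(df$start, path, "start"),
                    length = .parse_int(df$length, path, "length"),
                    sequence = df$sequence,
                    min_cross_distance = .parse_int(df$min_cross_distance,
                                                    path, "min_cross_distance",
                                                    allow_na = TRUE),
                    nearest_nontarget = df$nearest_nontarget,
                    dist_to_3prime = .parse_int(df$dist_to_3prime, path,
                                                "dist_to_3prime"),
                    stringsAsFactors = FALSE)
  out
}

.parse_int <- function(x, path, col, allow_na = FALSE) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & (!allow_na | !is.na(x)))
  if (length(bad) > 0L) {
    stop(sprintf("malformed value in column '%s' of %s at line %d",
                 col, path, bad[1L] + 1L), call. = FALSE)
  }
  out
}

.intensity_ceiling <- 2^20  # 20-bit scanner dynamic range

#' Read / write an intensity table
#'
#' Tab-separated with header `probe_id`, `sample_id`, `intensity`,
#' `detected`. Intensities are linear-scale, non-negative reals; values above
#' the 20-bit scanner ceiling (2^20 = 1,048,576) are clamped to it with a
#' warning on read. Negative intensities are an error.
#'
#' @param path File path.
#' @param records Data frame of intensity records to write.
#' @return A data frame of intensity records; `write_intensity_table()`
#'   returns `path` invisibly.
#' @export
read_intensity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "sample_id", "intensity", "detected")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("intensity table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(df$intensity))
  if (anyNA(val)) {
    stop(sprintf("malformed intensity in %s at line %d", path,
                 which(is.na(val))[1L] + 1L), call. = FALSE)
  }
  if (any(val < 0)) {
    stop(sprintf("negative intensity in %s at line %d", path,
                 which(val < 0)[1L] + 1L), call. = FALSE)
  }
  over <- val > .intensity_ceiling
  if (any(over)) {
    warning(sum(over), " intensity value(s) above the 2^20 ceiling clamped",
            call. = FALSE)
    val[over] <- .intensity_ceiling
  }
  data.frame(probe_id = df$probe_id, sample_id = df$sample_id,
             intensity = val, detected = as.logical(df$detected),
             stringsAsFactors = FALSE)
}

#' @rdname read_intensity_table
#' @export
write_intensity_table <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("probe_id", "sample_id", "intensity", "detected")
                %in% names(records)))
  if (any(records$intensity < 0)) stop("negative intensity", call. = FALSE)
  write.table(records[, c("probe_id", "sample_id", "intensity", "detected")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known-homolog table
#'
#' Two tab-separated columns, `gene_id_species_A` and `gene_id_species_B`,
#' listing gene pairs already known to be homologous (e.g. from a precomputed
#' sequence-similarity search).
#'
#' @param path File path.
#' @return Data frame with the two id columns.
#' @export
read_known_homologs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("gene_id_species_A", "gene_id_species_B")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("known-homolog table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df[, need]
}

#' Read a gene-annotation table
#'
#' Tab-separated columns `gene_id` and `annotation`.
#'
#' @param path File path.
#' @return Data frame with `gene_id` and `annotation`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(c("gene_id", "annotation"), names(df))
  if (length(miss) > 0L) {
    stop("annotation table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df[, c("gene_id", "annotation")]
}
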