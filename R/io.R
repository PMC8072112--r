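# Reading and writing the formats the pipeline touches: germline and clone
# FASTA, the sample sheet binding clones to mouse metadata, and the
# AIRR-flavoured rearrangement TSV that downstream stages consume.

#' Read germline V, D or J reference segments from FASTA
#'
#' Headers follow a minimal pipe-delimited dialect
#' `>name|subgroup|functionality`; the subgroup and functionality fields are
#' optional and extra fields are ignored. When the subgroup is absent it is
#' derived from the gene-name prefix (the part before the first `-`, `.` or
#' `*`). Sequences are uppercased and `U` is mapped to `T` (mRNA-derived
#' references).
#'
#' @param path Path to a FASTA file.
#' @param segment_type One of `"V"`, `"D"`, `"J"`.
#' @param allow_n If `TRUE`, `N` is tolerated in sequences; any other
#'   non-ACGT character is always rejected.
#' @return A tibble with one row per segment: `name`, `segment_type`,
#'   `subgroup`, `sequence`, `functionality`.
#' @export
read_germline_fasta <- function(path, segment_type = c("V", "D", "J"),
                                allow_n = FALSE) {
  segment_type <- match.arg(segment_type)
  recs <- read_fasta_checked(path)
  if (length(recs) == 0L) {
    warning("no records in FASTA file: ", path, call. = FALSE)
    return(tibble(name = character(), segment_type = character(),
                  subgroup = character(), sequence = character(),
                  functionality = character()))
  }
  fields <- strsplit(names(recs), "|", fixed = TRUE)
  name <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(name)) {
    stop_ighrep("duplicate gene name(s) in ", path, ": ",
                paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  subgroup <- vapply(fields, function(f) {
    if (length(f) >= 2L && nzchar(f[2L])) f[2L] else NA_character_
  }, character(1))
  functionality <- vapply(fields, function(f) {
    if (length(f) >= 3L && nzchar(f[3L])) f[3L] else "unknown"
  }, character(1))
  seqs <- chartr("U", "T", toupper(as.character(recs)))
  check_nt(seqs, paste0(segment_type, "-segment sequence"), allow_n = allow_n)
  out <- tibble(
    name = unname(name),
    segment_type = segment_type,
    subgroup = ifelse(is.na(subgroup), segment_subgroup(name), subgroup),
    sequence = unname(seqs),
    functionality = ifelse(functionality %in% c("F", "P", "ORF"),
                           functionality, "unknown")
  )
  validate_germline(out)
  out
}

# Light structural pre-check so malformed FASTA fails with a line number,
# then delegate actual parsing to Biostrings.
read_fasta_checked <- function(path) {
  if (!file.exists(path)) stop_ighrep("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) > 0L && !startsWith(lines[nonempty[1L]], ">")) {
    stop_ighrep("malformed FASTA at line ", nonempty[1L], " of ", path,
                ": expected a '>' header")
  }
  if (length(nonempty) == 0L) {
    return(Biostrings::BStringSet())
  }
  Biostrings::readBStringSet(path)
}

validate_germline <- function(g) {
  lens <- nchar(g$sequence)
  bounds <- list(V = c(100L, Inf), D = c(5L, 40L), J = c(20L, 80L))
  for (ty in unique(g$segment_type)) {
    b <- bounds[[ty]]
    bad <- g$segment_type == ty & (lens < b[1L] | lens > b[2L])
    if (any(bad)) {
      stop_ighrep(ty, " segment length out of range [", b[1L], ", ", b[2L],
                  "]: ", paste(g$name[bad], collapse = ", "))
    }
  }
  invisible(g)
}

#' Read a sample sheet
#'
#' Tab-separated file with header
#' `record_id  mouse_id  genotype  tissue  is_allotransplant  parental_mouse_id`
#' mapping FASTA record IDs to cohort metadata. `parental_mouse_id` must be
#' set exactly for allotransplanted (F1 recipient) records.
#'
#' @param path Path to the TSV sample sheet.
#' @return A tibble with the sheet columns, types coerced.
#' @export
read_sample_sheet <- function(path) {
  sheet <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                                colClasses = "character"))
  needed <- c("record_id", "mouse_id", "genotype", "tissue",
              "is_allotransplant", "parental_mouse_id")
  missing <- setdiff(needed, names(sheet))
  if (length(missing) > 0L) {
    stop_ighrep("sample sheet is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  sheet$is_allotransplant <- toupper(sheet$is_allotransplant) %in%
    c("TRUE", "T", "1", "YES")
  sheet$parental_mouse_id[!nzchar(sheet$parental_mouse_id %||% "")] <- NA_character_
  if (anyDuplicated(sheet$record_id)) {
    stop_ighrep("duplicate record_id in sample sheet: ",
                paste(unique(sheet$record_id[duplicated(sheet$record_id)]),
                      collapse = ", "))
  }
  if (any(!sheet$genotype %in% GENOTYPES)) {
    stop_ighrep("genotype must be one of ", paste(GENOTYPES, collapse = " "))
  }
  bad <- sheet$is_allotransplant != !is.na(sheet$parental_mouse_id)
  if (any(bad)) {
    stop_ighrep("parental_mouse_id must be set iff is_allotransplant: ",
                paste(sheet$record_id[bad], collapse = ", "))
  }
  sheet
}

#' Read clone sequences and bind them to cohort metadata
#'
#' Each FASTA record is a sequenced colony (or a set of identical colonies
#' when `colony_count` says so). Every FASTA ID must be covered by the sample
#' sheet.
#'
#' @param path Path to the clone FASTA.
#' @param sheet Sample sheet tibble from [read_sample_sheet()].
#' @return A tibble of clone records: `record_id`, `mouse_id`, `genotype`,
#'   `tissue`, `is_allotransplant`, `parental_mouse_id`, `sequence`,
#'   `colony_count` (defaults to 1).
#' @export
read_clone_fasta <- function(path, sheet) {
  recs <- read_fasta_checked(path)
  ids <- sub("\\s.*$", "", names(recs))
  unmapped <- setdiff(ids, sheet$record_id)
  if (length(unmapped) > 0L) {
    stop_ighrep("FASTA record(s) missing from sample sheet: ",
                paste(unmapped, collapse = ", "))
  }
  seqs <- chartr("U", "T", toupper(as.character(recs)))
  check_nt(seqs, "clone sequence")
  if (any(nchar(seqs) < 150L)) {
    stop_ighrep("clone sequences must be >= 150 nt: ",
                paste(ids[nchar(seqs) < 150L], collapse = ", "))
  }
  out <- tibble(record_id = ids, sequence = unname(seqs)) %>%
    left_join(sheet, by = "record_id")
  out$colony_count <- if ("colony_count" %in% names(sheet)) {
    as.integer(out$colony_count)
  } else {
    1L
  }
  out[, c("record_id", "mouse_id", "genotype", "tissue", "is_allotransplant",
          "parental_mouse_id", "sequence", "colony_count")]
}

#' Write the rearrangement table
#'
#' Tab-separated, AIRR-flavoured table of annotated clones (one row per clone
#' record). An absent D call is written as an empty string. Round-trips
#' losslessly through [read_rearrangement_table()].
#'
#' @param annotations Tibble carrying at least the columns listed by
#'   `ighrep:::rearrangement_columns()`; extra (e.g. list) columns are
#'   dropped on write.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_rearrangement_table <- function(annotations, path) {
  cols <- rearrangement_columns()
  missing <- setdiff(cols, names(annotations))
  if (length(missing) > 0L) {
    stop_ighrep("annotations are missing column(s): ",
                paste(missing, collapse = ", "))
  }
  out <- as.data.frame(annotations[, cols])
  for (col in c("d_call", "parental_mouse_id")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a rearrangement table
#'
#' Inverse of [write_rearrangement_table()]; also accepts pre-annotated
#' tables produced elsewhere, provided they carry the same column set.
#'
#' @param path Path to the TSV.
#' @return A tibble with typed columns.
#' @export
read_rearrangement_table <- function(path) {
  df <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character", na.strings = "NA"))
  missing <- setdiff(rearrangement_columns(), names(df))
  if (length(missing) > 0L) {
    stop_ighrep("rearrangement table is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  df$d_call[!is.na(df$d_call) & !nzchar(df$d_call)] <- NA_character_
  df$parental_mouse_id[!is.na(df$parental_mouse_id) &
                         !nzchar(df$parental_mouse_id)] <- NA_character_
  for (col in c("v_identity", "shm_percent")) df[[col]] <- as.numeric(df[[col]])
  for (col in c("ssp_count", "shm_count", "colony_count")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("productive", "is_allotransplant")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Write a set of germline segments as FASTA
#'
#' Uses the pipe-delimited header dialect `>name|subgroup|functionality`.
#'
#' @param germline Germline tibble (as from [read_germline_fasta()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_germline_fasta <- function(germline, path) {
  seqs <- Biostrings::DNAStringSet(germline$sequence)
  names(seqs) <- paste(germline$name, germline$subgroup,
                       germline$functionality, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Load the packaged table of expanded CLL/SLL clones
#'
#' Transcription of the published table of expanded clones from the
#' double-transgenic mouse CLL/SLL cohort: per-clone tissue, gene calls
#' (IMGT and VBASE2 nomenclature), SHM percent and status, colony frequency,
#' and the HCDR3 sequence with its printed length and pI. Used as a packaged
#' input for the deduplication, stereotypy and feature stages, and as the
#' reference the package's own computations are checked against.
#'
#' @return A tibble, one row per printed clone entry (27 rows). `v_call`
#'   carries the VBASE2 gene name where known, otherwise the IMGT allele.
#' @export
load_expanded_clones <- function() {
  path <- system.file("extdata", "expanded_clones.tsv", package = "ighrep",
                      mustWork = TRUE)
  df <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character"))
  df$is_allotransplant <- df$is_allotransplant == "TRUE"
  df$parental_mouse_id[!nzchar(df$parental_mouse_id)] <- NA_character_
  df$shm_percent <- as.numeric(df$shm_percent)
  df$colony_count <- as.integer(df$colony_count)
  df$sample_total <- as.integer(df$sample_total)
  df$percent_printed <- as.numeric(df$percent_printed)
  df$cdr3_length <- as.integer(df$cdr3_length)
  df$pI <- as.numeric(df$pI)
  df$v_call <- ifelse(df$v_call_vbase2 == "Unknown", df$v_call_imgt,
                      df$v_call_vbase2)
  df
}
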