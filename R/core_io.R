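# Genome/feature data model and readers/writers for FASTA, GFF3, GenBank
# flat files, and TSV tables. Coordinates are 1-based inclusive throughout
# (GenBank convention); GFF3 input already uses that convention and
# minus-strand CDS sequences are stored reverse-complemented onto the
# coding strand.

.feature_cols <- c("feature_id", "genome_id", "contig_id", "start", "end",
                   "strand", "product", "cds", "is_pseudo")

#' Construct a validated genome record
#'
#' @param genome_id Genome identifier.
#' @param contigs Named character vector of contig sequences.
#' @param features Data frame of gene features with columns `feature_id`,
#'   `genome_id`, `contig_id`, `start`, `end`, `strand` (`+`/`-`),
#'   `product`, `cds` (coding-strand sequence), `is_pseudo`.
#' @param metadata Free-form list (host species, supergroup, assembly
#'   status, provenance).
#' @return A `genome_record`.
#' @export
genome_record <- function(genome_id, contigs, features = NULL, metadata = list()) {
  stopifnot(is.character(contigs), length(names(contigs)) == length(contigs))
  contigs <- toupper(contigs)
  if (is.null(features) || nrow(features) == 0) {
    features <- tibble(
      feature_id = character(), genome_id = character(),
      contig_id = character(), start = integer(), end = integer(),
      strand = character(), product = character(), cds = character(),
      is_pseudo = logical()
    )
  }
  features <- as_tibble(features)[, .feature_cols]
  if (anyDuplicated(features$feature_id)) {
    abort("feature_ids must be unique within a genome")
  }
  if (any(features$start > features$end)) {
    abort("feature start must not exceed end (1-based inclusive coordinates)")
  }
  for (i in seq_len(nrow(features))) {
    ctg <- features$contig_id[i]
    if (!ctg %in% names(contigs)) {
      abort(sprintf("feature %s references unknown contig %s",
                    features$feature_id[i], ctg))
    }
    if (features$end[i] > nchar(contigs[[ctg]])) {
      abort(sprintf("feature %s extends beyond contig %s",
                    features$feature_id[i], ctg))
    }
  }
  structure(
    list(genome_id = genome_id, contigs = contigs, features = features,
         metadata = metadata),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("Genome %s: %d contig(s), %s bp, %d feature(s)\n",
              x$genome_id, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

#' Extract a region from a genome (1-based inclusive)
#'
#' @param genome A `genome_record`.
#' @param contig_id Contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return Nucleotide string.
#' @examples
#' g <- genome_record("g", c(c1 = "ACGTACGTA"))
#' extract_region(g, "c1", 5, 7) # "ACG"
#' @export
extract_region <- function(genome, contig_id, start, end) {
  if (!contig_id %in% names(genome$contigs)) {
    abort(sprintf("unknown contig \"%s\"", contig_id))
  }
  L <- nchar(genome$contigs[[contig_id]])
  if (start < 1 || end > L || start > end) {
    abort(sprintf("span [%d, %d] out of range for contig %s (length %d)",
                  start, end, contig_id, L))
  }
  substr(genome$contigs[[contig_id]], start, end)
}

#' Which features are admissible for codon analysis
#'
#' A feature enters codon analysis when it is not a pseudogene (unless
#' `include_pseudo`), its CDS length is divisible by 3, and it carries no
#' internal stop codon. Exclusions are logged with a reason.
#'
#' @param features Feature tibble (as in [genome_record()]).
#' @param include_pseudo Keep pseudogenes (default FALSE).
#' @inheritParams sense_codons
#' @return The admissible subset of `features`, with the excluded rows and
#'   reasons attached as `attr(x, "excluded")`.
#' @export
codon_admissible <- function(features, include_pseudo = FALSE,
                             code = Biostrings::GENETIC_CODE) {
  features <- as_tibble(features)
  reason <- rep(NA_character_, nrow(features))
  for (i in seq_len(nrow(features))) {
    cds <- toupper(features$cds[i])
    if (features$is_pseudo[i] && !include_pseudo) {
      reason[i] <- "pseudogene"
    } else if (nchar(cds) %% 3L != 0L) {
      reason[i] <- "length not divisible by 3"
    } else {
      n <- nchar(cds) %/% 3L
      starts <- 3L * (seq_len(n) - 1L) + 1L
      codons <- substring(cds, starts, starts + 2L)
      internal <- head(codons, -1L)
      clean <- grepl("^[ACGT]{3}$", internal)
      if (any(code[internal[clean]] == "*")) {
        reason[i] <- "internal stop codon"
      }
    }
  }
  excluded <- filter(mutate(features, reason = reason), !is.na(reason))
  for (i in seq_len(nrow(excluded))) {
    ph_log("core_io", sprintf("feature %s excluded from codon analysis: %s",
                              excluded$feature_id[i], excluded$reason[i]),
           force = TRUE)
  }
  out <- filter(features, is.na(reason))
  attr(out, "excluded") <- excluded
  out
}

#' Read an annotated genome
#'
#' Supported formats: `"fasta+gff3"` (a FASTA of contigs plus a GFF3 of
#' features; requires `gff`) and `"genbank"` (a flat file with LOCUS /
#' FEATURES / ORIGIN sections; simple and `complement(...)` CDS locations).
#' All CDS features carry coding-strand sequence and 1-based inclusive
#' coordinates.
#'
#' @param path FASTA file (for `fasta+gff3`) or GenBank flat file.
#' @param format `"fasta+gff3"` or `"genbank"`.
#' @param gff GFF3 path (required for `fasta+gff3`).
#' @param genome_id Identifier (defaults to the file name / LOCUS).
#' @return A [genome_record()].
#' @export
read_genome <- function(path, format = c("fasta+gff3", "genbank"),
                        gff = NULL, genome_id = NULL) {
  format <- match.arg(format)
  if (format == "fasta+gff3") {
    if (is.null(gff)) abort("`gff` is required for format \"fasta+gff3\"")
    .read_fasta_gff3(path, gff, genome_id)
  } else {
    .read_genbank(path, genome_id)
  }
}

.cds_from_contig <- function(contig_seq, start, end, strand) {
  s <- substr(contig_seq, start, end)
  if (strand == "-") revcomp(s) else s
}

.read_fasta_gff3 <- function(fasta_path, gff_path, genome_id) {
  contigs_xs <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- setNames(as.character(contigs_xs),
                      sub("\\s.*$", "", names(contigs_xs)))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("CDS", "gene", "pseudogene"), , drop = FALSE]
  df <- df[df$type == "CDS" | !(df$ID %in% df$Parent), , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))
  }
  feats <- purrr::map(seq_len(nrow(cds)), function(i) {
    ctg <- as.character(cds$seqnames[i])
    if (!ctg %in% names(contigs)) {
      abort(sprintf("GFF3 record %d references unknown contig %s", i, ctg))
    }
    if (cds$end[i] > nchar(contigs[[ctg]]) || cds$start[i] < 1) {
      abort(sprintf("feature %s lies outside contig %s",
                    cds$ID[i] %||% i, ctg))
    }
    strand <- as.character(cds$strand[i])
    if (!strand %in% c("+", "-")) strand <- "+"
    id <- cds$ID[i]
    if (is.null(id) || is.na(id)) id <- sprintf("cds_%04d", i)
    pseudo <- "pseudo" %in% names(cds) && !is.na(cds$pseudo[i])
    tibble(
      feature_id = as.character(id), genome_id = genome_id, contig_id = ctg,
      start = as.integer(cds$start[i]), end = as.integer(cds$end[i]),
      strand = strand,
      product = if ("product" %in% names(cds) && !is.na(cds$product[i])) {
        as.character(cds$product[i])
      } else "",
      cds = .cds_from_contig(contigs[[ctg]], cds$start[i], cds$end[i], strand),
      is_pseudo = pseudo
    )
  })
  genome_record(genome_id, contigs, bind_rows(feats),
                metadata = list(source = fasta_path))
}

# Minimal GenBank flat-file parser: LOCUS name, FEATURES CDS entries with
# simple or complement() locations, /locus_tag, /product, /pseudo
# qualifiers, and the ORIGIN sequence block.
.read_genbank <- function(path, genome_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) abort(sprintf("%s: not a GenBank flat file (no LOCUS line)", path))
  origin_i <- grep("^ORIGIN", lines)
  features_i <- grep("^FEATURES", lines)
  if (!length(origin_i) || !length(features_i)) {
    abort(sprintf("%s: missing FEATURES or ORIGIN section", path))
  }
  locus_name <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1]])), "\\s+")[[1]][1]
  if (is.null(genome_id)) genome_id <- locus_name
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  contig_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat_lines <- lines[(features_i[1] + 1L):(origin_i[1] - 1L)]
  # a feature starts at indent 5; qualifiers/continuations at indent 21
  starts <- grep("^ {5}\\S", feat_lines)
  feats <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1L] - 1L else length(feat_lines)
    block <- feat_lines[from:to]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]]
    if (key[1] != "CDS") next
    loc <- paste0(key[-1], collapse = "")
    qual_start <- grep("^\\s+/", block)
    first_q <- if (length(qual_start)) min(qual_start) else length(block) + 1L
    if (first_q > 2L) {
      loc <- paste0(loc, paste0(trimws(block[2:(first_q - 1L)]), collapse = ""))
    }
    strand <- "+"
    loc_clean <- loc
    if (grepl("^complement\\(", loc_clean)) {
      strand <- "-"
      loc_clean <- sub("^complement\\((.*)\\)$", "\\1", loc_clean)
    }
    if (grepl("join|order", loc_clean)) {
      abort(sprintf("%s: compound location \"%s\" not supported", path, loc))
    }
    m <- regmatches(loc_clean, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc_clean))[[1]]
    if (length(m) != 3) {
      abort(sprintf("%s: cannot parse CDS location \"%s\"", path, loc))
    }
    start <- as.integer(m[2])
    end <- as.integer(m[3])
    qual <- paste(trimws(block[-1]), collapse = " ")
    get_q <- function(name) {
      mm <- regmatches(qual, regexec(sprintf('/%s="([^"]*)"', name), qual))[[1]]
      if (length(mm) == 2) mm[2] else NA_character_
    }
    locus_tag <- get_q("locus_tag")
    if (is.na(locus_tag)) locus_tag <- get_q("gene")
    if (is.na(locus_tag)) locus_tag <- sprintf("cds_%04d", length(feats) + 1L)
    product <- get_q("product")
    if (is.na(product)) product <- ""
    if (end > nchar(contig_seq)) {
      abort(sprintf("%s: feature %s outside contig (end %d > length %d)",
                    path, locus_tag, end, nchar(contig_seq)))
    }
    feats[[length(feats) + 1L]] <- tibble(
      feature_id = locus_tag, genome_id = genome_id, contig_id = locus_name,
      start = start, end = end, strand = strand,
      product = product,
      cds = .cds_from_contig(contig_seq, start, end, strand),
      is_pseudo = grepl("/pseudo\\b", qual)
    )
  }
  genome_record(genome_id, setNames(contig_seq, locus_name),
                if (length(feats)) bind_rows(feats) else NULL,
                metadata = list(source = path))
}

#' Write a genome record as FASTA + GFF3
#'
#' @param genome A `genome_record`.
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  xs <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(xs, fasta_path)
  f <- genome$features
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(f))) {
    attrs <- sprintf("ID=%s;product=%s", f$feature_id[i],
                     gsub("[;=\t]", " ", f$product[i]))
    if (f$is_pseudo[i]) attrs <- paste0(attrs, ";pseudo=true")
    lines <- c(lines, paste(
      f$contig_id[i], "phagehgt", "CDS", f$start[i], f$end[i], ".",
      f$strand[i], "0", attrs,
      sep = "\t"
    ))
  }
  writeLines(lines, gff_path)
  invisible(c(fasta_path, gff_path))
}

#' Write a table as TSV
#'
#' @param rows Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  readr::write_tsv(as_tibble(rows), path)
  invisible(path)
}

#' Read an ortholog pair table
#'
#' Header-keyed TSV with at least `gene_a` and `gene_b` columns (column
#' order is irrelevant); extra columns are kept.
#'
#' @param path TSV path.
#' @return Tibble of pairs (possibly empty).
#' @export
read_ortholog_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(c("gene_a", "gene_b"), names(tb))
  if (length(missing)) {
    abort(sprintf("ortholog table %s lacks required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  tb
}

#' Read a JSON run configuration into a simulation config
#'
#' @param path JSON file whose top-level keys match [sim_config()]
#'   arguments.
#' @return A `sim_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, raw[intersect(names(raw), names(formals(sim_config)))])
}
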