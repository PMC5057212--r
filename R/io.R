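# All internal coordinates are 0-based half-open in transcript space.
# GFF3 I/O converts to/from 1-based closed intervals at the boundary;
# bedGraph stays 0-based half-open.

#' Read transcript models from GFF3 + FASTA
#'
#' Reads gene models (features `gene`, `mRNA`, `five_prime_UTR`, `CDS`,
#' `three_prime_UTR` in transcript space) and their sequences, keeping the
#' longest mRNA per gene. Models violating the structural invariants
#' (contiguous UTR5/CDS/UTR3, CDS divisible by 3, intervals within the
#' sequence) are skipped with a warning naming the reason.
#'
#' @param gff3_path Path to a GFF3 annotation whose seqids are transcript ids.
#' @param fasta_path Path to the matching transcript FASTA.
#' @return Tibble of transcript models.
#' @export
read_transcript_models <- function(gff3_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  if (nrow(df) == 0) return(empty_models())

  mrna <- df %>% filter(.data$type == "mRNA")
  if (nrow(mrna) == 0) return(empty_models())
  mrna <- mrna %>%
    mutate(gene_id = vapply(.data$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1)),
      len = .data$end - .data$start + 1) %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(.data$len), .data$ID) %>%
    slice(1) %>%
    ungroup()

  out <- purrr::pmap(
    list(mrna$ID, mrna$gene_id, as.character(mrna$seqnames)),
    function(tx_id, gene_id, seqname) {
      if (!seqname %in% names(seqs)) {
        abort(sprintf("missing sequence for transcript '%s'", seqname))
      }
      sq <- as.character(seqs[[seqname]])
      feats <- df %>%
        filter(vapply(.data$Parent, function(p)
          any(as.character(p) == tx_id), logical(1)))
      iv <- function(type) {
        f <- feats %>% filter(.data$type == !!type) %>% arrange(.data$start)
        if (nrow(f) == 0) return(NULL)
        c(min(f$start) - 1L, max(f$end))     # 1-based closed -> 0-based half-open
      }
      cds <- iv("CDS"); u5 <- iv("five_prime_UTR"); u3 <- iv("three_prime_UTR")
      L <- nchar(sq)
      skip <- function(why) {
        warn(sprintf("skipping %s: %s", tx_id, why)); NULL
      }
      if (is.null(cds)) return(skip("no CDS"))
      if (is.null(u5)) u5 <- c(0L, cds[1])
      if (is.null(u3)) u3 <- c(cds[2], L)
      if ((cds[2] - cds[1]) %% 3 != 0) return(skip("CDS not divisible by 3"))
      if (u5[2] != cds[1] || cds[2] != u3[1]) return(skip("regions not contiguous"))
      if (u5[1] != 0 || u3[2] > L) return(skip("intervals outside sequence"))
      meta <- function(col, default) {
        v <- mrna[[col]][mrna$ID == tx_id]
        if (is.null(v) || length(v) == 0 || is.na(v[1])) default else as.character(v[1])
      }
      tibble(gene_id = gene_id, transcript_id = tx_id, sequence = sq,
             utr5_start = u5[1], utr5_end = u5[2],
             cds_start = cds[1], cds_end = cds[2],
             utr3_start = u3[1], utr3_end = u3[2], length = L,
             compartment = meta("compartment", "nuclear"),
             operon_id = {
               v <- meta("operon_id", NA_character_)
               if (identical(v, "NA")) NA_character_ else v
             })
    })
  out <- bind_rows(out)
  if (nrow(out) == 0) empty_models() else out
}

empty_models <- function() {
  tibble(gene_id = character(), transcript_id = character(),
         sequence = character(), utr5_start = integer(), utr5_end = integer(),
         cds_start = integer(), cds_end = integer(), utr3_start = integer(),
         utr3_end = integer(), length = integer(), compartment = character(),
         operon_id = character())
}

#' Write transcript models as GFF3 + FASTA
#'
#' @param models Transcript model tibble.
#' @param gff3_path,fasta_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_transcript_models <- function(models, gff3_path, fasta_path) {
  assert_models(models)
  seqs <- Biostrings::DNAStringSet(setNames(models$sequence, models$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_path)

  one <- function(m) {
    # 0-based half-open -> 1-based closed
    feat <- function(type, s, e, id = NA, parent = NA) {
      tibble(seqnames = m$transcript_id, start = s + 1L, end = e,
             type = type, ID = id, Parent = parent)
    }
    bind_rows(
      feat("gene", 0L, m$length, id = m$gene_id),
      feat("mRNA", 0L, m$length, id = m$transcript_id, parent = m$gene_id),
      if (m$utr5_end > m$utr5_start)
        feat("five_prime_UTR", m$utr5_start, m$utr5_end,
             id = paste0(m$transcript_id, ".utr5"), parent = m$transcript_id),
      feat("CDS", m$cds_start, m$cds_end,
           id = paste0(m$transcript_id, ".cds"), parent = m$transcript_id),
      if (m$utr3_end > m$utr3_start)
        feat("three_prime_UTR", m$utr3_start, m$utr3_end,
             id = paste0(m$transcript_id, ".utr3"), parent = m$transcript_id)
    )
  }
  feats <- bind_rows(purrr::map(seq_len(nrow(models)), function(i) one(models[i, ])))
  gr <- GenomicRanges::GRanges(
    seqnames = feats$seqnames,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = "+", type = feats$type, ID = feats$ID,
    Parent = ifelse(is.na(feats$Parent), NA, feats$Parent),
    phase = ifelse(feats$type == "CDS", 0L, NA_integer_))
  meta <- models %>% select("transcript_id", "compartment", "operon_id")
  idx <- match(as.character(GenomicRanges::seqnames(gr)), meta$transcript_id)
  is_mrna <- gr$type == "mRNA"
  gr$compartment <- ifelse(is_mrna, meta$compartment[idx], NA)
  gr$operon_id <- ifelse(is_mrna, as.character(meta$operon_id[idx]), NA)
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(list(gff3 = gff3_path, fasta = fasta_path))
}

#' Read / write transcript-space read records as TSV
#'
#' Columns: `transcript_id`, `five_prime_pos_0based`, `read_length`; sample
#' metadata travels in the file name by convention and is supplied explicitly
#' on read.
#'
#' @param reads Read tibble (one sample).
#' @param path TSV path.
#' @param sample_id,assay,condition,replicate Sample metadata attached on read.
#' @return `write_reads_tsv()` the path, invisibly; `read_reads_tsv()` a read
#'   tibble.
#' @export
write_reads_tsv <- function(reads, path) {
  assert_reads(reads)
  readr::write_tsv(
    reads %>% select(transcript_id = "transcript_id",
                     five_prime_pos_0based = "pos", read_length = "length"),
    path)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path, sample_id, assay, condition, replicate = 1L) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  tibble(sample_id = sample_id, assay = assay, condition = condition,
         replicate = replicate,
         transcript_id = df$transcript_id,
         pos = as.integer(df$five_prime_pos_0based),
         length = as.integer(df$read_length))
}

#' Per-position read depth in transcript space
#'
#' Depth at position p counts the reads whose interval
#' `[five_prime, five_prime + length)` contains p; reads overhanging the
#' transcript end are clipped at the boundary. Rows of `reads` referencing
#' unknown transcripts are skipped with a message giving the count. Reads
#' from all rows supplied are pooled; filter by sample or condition first.
#'
#' @param reads Read tibble.
#' @param models Transcript model tibble.
#' @return Tibble with `transcript_id`, `length`, and a `depth` list-column
#'   of integer per-position depth vectors.
#' @export
coverage_from_reads <- function(reads, models) {
  assert_models(models)
  unknown <- !(reads$transcript_id %in% models$transcript_id)
  if (any(unknown)) {
    inform(sprintf("coverage_from_reads: skipped %d reads on unknown transcripts",
                   sum(unknown)))
    reads <- reads[!unknown, ]
  }
  len <- setNames(models$length, models$transcript_id)
  by_tx <- split(reads[c("pos", "length")], reads$transcript_id)
  depth <- purrr::imap(by_tx, function(r, tx) {
    L <- len[[tx]]
    starts <- pmax(pmin(r$pos, L), 0L)
    ends <- pmin(r$pos + r$length, L)
    keep <- ends > starts
    d <- integer(L + 1L)
    ts <- table(starts[keep]); te <- table(ends[keep])
    d[as.integer(names(ts)) + 1L] <- d[as.integer(names(ts)) + 1L] + as.integer(ts)
    d[as.integer(names(te)) + 1L] <- d[as.integer(names(te)) + 1L] - as.integer(te)
    head(cumsum(d), L)
  })
  tibble(transcript_id = names(depth),
         length = as.integer(len[names(depth)]),
         depth = unname(depth))
}

#' Export per-transcript coverage as bedGraph
#'
#' 0-based half-open intervals with constant depth, one track per call.
#'
#' @param coverage Result of [coverage_from_reads()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  rows <- purrr::pmap(list(coverage$transcript_id, coverage$depth),
                      function(tx, d) {
    r <- rle(d)
    e <- cumsum(r$lengths)
    s <- c(0L, head(e, -1))
    keep <- r$values != 0
    tibble(chrom = tx, start = s[keep], end = e[keep], value = r$values[keep])
  })
  readr::write_tsv(bind_rows(rows), path, col_names = FALSE)
  invisible(path)
}

#' Write planted ground truth as JSON
#'
#' @param truth The `truth` element of [simulate_transcriptome()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth[setdiff(names(truth), "config")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
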