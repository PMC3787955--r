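#' Reading and writing pipeline tables
#'
#' Delimited-text I/O for CNV calls, CNVR tables, feature annotations (BED
#' and GFF-like), genotype matrices, sample sheets and qPCR CT tables.
#' Coordinate conventions are never guessed: BED input is declared 0-based
#' half-open and converted at the boundary; everything else must be declared
#' 1-based inclusive. Internally everything is 1-based inclusive.
#'
#' @name io
NULL

.default_state_synonyms <- c(
  gain = "gain", loss = "loss",
  duplication = "gain", dup = "gain", amplification = "gain",
  deletion = "loss", del = "loss",
  "0" = "loss", "1" = "loss", "3" = "gain", "4" = "gain", "5" = "gain"
)

#' Default caller state vocabulary
#'
#' Maps caller state tokens (including copy-number integers: 0,1 -> loss;
#' 3+ -> gain) onto the canonical `{gain, loss}` vocabulary.
#' @return named character vector, names are accepted tokens.
#' @export
default_state_synonyms <- function() .default_state_synonyms

.resolve_state <- function(state, synonyms, file = "<data>") {
  key <- tolower(trimws(as.character(state)))
  out <- unname(synonyms[key])
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf(
      "%s: unknown state token '%s' at line %d; accepted: %s",
      file, state[bad[1]], bad[1],
      paste(unique(names(synonyms)), collapse = ", ")))
  out
}

.read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read per-algorithm CNV calls
#'
#' @param path delimited text file with columns `sample`, `chrom`, `start`,
#'   `end`, `state`, `n_snps` (extra columns, e.g. `copy_number`, are kept).
#' @param algorithm_id identifier of the calling algorithm, attached to
#'   every row.
#' @param coords coordinate convention of the file: `"1-based"` (inclusive)
#'   or `"bed"` (0-based half-open). There is no default: the convention
#'   must be declared.
#' @param sep field separator; autodetected (tab vs comma) when NULL.
#' @param state_synonyms named map of accepted state tokens to
#'   `gain`/`loss`; see [default_state_synonyms()].
#' @return data frame of validated calls: `sample_id`, `algorithm_id`,
#'   `chrom`, `start`, `end`, `state`, `n_snps` (+ `copy_number` if present).
#' @export
read_cnv_calls <- function(path, algorithm_id, coords = c("1-based", "bed"),
                           sep = NULL,
                           state_synonyms = default_state_synonyms()) {
  coords <- match.arg(coords)
  df <- .read_delim_auto(path, sep)
  cols <- c(sample = "sample", chrom = "chrom", start = "start",
            end = "end", state = "state", n_snps = "n_snps")
  miss <- setdiff(unname(cols), names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    sample_id = as.character(df$sample),
    algorithm_id = algorithm_id,
    chrom = normalize_chrom(df$chrom),
    start = as.numeric(df$start),
    end = as.numeric(df$end),
    state = .resolve_state(df$state, state_synonyms, path),
    n_snps = as.integer(df$n_snps),
    stringsAsFactors = FALSE
  )
  if (coords == "bed") out$start <- out$start + 1
  if ("copy_number" %in% names(df))
    out$copy_number <- as.integer(df$copy_number)
  bad <- which(out$end < out$start | out$start < 1)
  if (length(bad))
    stop(sprintf("%s: line %d: invalid interval [%s, %s]",
                 path, bad[1], out$start[bad[1]], out$end[bad[1]]))
  bad <- which(is.na(out$n_snps) | out$n_snps < 1)
  if (length(bad))
    stop(sprintf("%s: line %d: n_snps must be >= 1", path, bad[1]))
  out
}

#' Write CNV calls
#'
#' Writes 1-based inclusive coordinates; round-trips with
#' [read_cnv_calls()].
#'
#' @param calls data frame from [read_cnv_calls()] or the simulator.
#' @param path output path (tab-separated).
#' @export
write_cnv_calls <- function(calls, path) {
  out <- data.frame(sample = calls$sample_id, chrom = calls$chrom,
                    start = calls$start, end = calls$end,
                    state = calls$state, n_snps = calls$n_snps)
  if ("copy_number" %in% names(calls)) out$copy_number <- calls$copy_number
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read feature annotations (genes, QTLs, SNPs, DGV regions, assembly gaps)
#'
#' @param path BED or delimited file. BED (`coords = "bed"`): columns
#'   chrom/start/end[/name[/...]] without header, 0-based half-open,
#'   converted on read. Tabular (`coords = "1-based"`): header with
#'   `chrom`, `start`, `end` and optionally `feature_id` plus arbitrary
#'   attribute columns (e.g. `biotype`, `trait`).
#' @param kind one of `gene`, `qtl`, `snp`, `dgv_region`, `gap`.
#' @param coords `"bed"` or `"1-based"`; must be declared, never guessed.
#' @param sep separator for tabular input (autodetected when NULL).
#' @return data frame: `feature_id`, `chrom`, `start`, `end`, `kind`, plus
#'   attribute columns.
#' @export
read_features <- function(path, kind = c("gene", "qtl", "snp",
                                         "dgv_region", "gap"),
                          coords, sep = NULL) {
  kind <- match.arg(kind)
  if (missing(coords))
    stop("read_features: coordinate convention not declared; ",
         "pass coords = \"bed\" (0-based half-open) or \"1-based\"")
  coords <- match.arg(coords, c("bed", "1-based"))
  if (coords == "bed") {
    df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, comment.char = "#")
    out <- data.frame(
      feature_id = if (ncol(df) >= 4) as.character(df[[4]])
                   else paste0(kind, "_", seq_len(nrow(df))),
      chrom = normalize_chrom(df[[1]]),
      start = as.numeric(df[[2]]) + 1,  # 0-based half-open -> 1-based incl.
      end = as.numeric(df[[3]]),
      kind = kind, stringsAsFactors = FALSE)
  } else {
    df <- .read_delim_auto(path, sep)
    if (!all(c("chrom", "start", "end") %in% names(df)))
      stop(path, ": need columns chrom, start, end")
    out <- data.frame(
      feature_id = if ("feature_id" %in% names(df))
                     as.character(df$feature_id)
                   else paste0(kind, "_", seq_len(nrow(df))),
      chrom = normalize_chrom(df$chrom),
      start = as.numeric(df$start), end = as.numeric(df$end),
      kind = kind, stringsAsFactors = FALSE)
    extra <- setdiff(names(df), c("feature_id", "chrom", "start", "end"))
    for (nm in extra) out[[nm]] <- df[[nm]]
  }
  if (kind == "snp" && any(out$start != out$end))
    stop(path, ": snp features must have start == end")
  validate_intervals(out, path)
  out
}

#' Write a CNVR table in the published layout
#'
#' Columns `CNVR NO. / Chr / Start / End / Length (Kb) / Status / Breed`;
#' the length column uses the published `(end - start)/1000` convention
#' (see [length_kb_published()]).
#'
#' @param cnvrs data frame with `cnvr_id`, `chrom`, `start`, `end`,
#'   `status`, and optionally `breed`.
#' @param path output path (tab-separated).
#' @export
write_cnvrs <- function(cnvrs, path) {
  status_label <- c(gain = "Gain", loss = "Loss", "gain-loss" = "Gain-Loss")
  out <- data.frame(
    check.names = FALSE,
    "CNVR NO." = if (nrow(cnvrs)) cnvrs$cnvr_id else integer(0),
    Chr = if (nrow(cnvrs)) cnvrs$chrom else character(0),
    Start = if (nrow(cnvrs)) cnvrs$start else numeric(0),
    End = if (nrow(cnvrs)) cnvrs$end else numeric(0),
    "Length (Kb)" = if (nrow(cnvrs))
      round_half_up(length_kb_published(cnvrs$start, cnvrs$end), 3)
      else numeric(0),
    Status = if (nrow(cnvrs)) unname(status_label[cnvrs$status])
             else character(0),
    Breed = if (nrow(cnvrs) && "breed" %in% names(cnvrs)) cnvrs$breed
            else if (nrow(cnvrs)) "" else character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a CNVR table written by [write_cnvrs()] (or the published layout)
#'
#' @param path tab-separated file in the published column layout.
#' @return data frame `cnvr_id`, `chrom`, `start`, `end`, `status`,
#'   `breed`, `length_kb`.
#' @export
read_cnvrs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  status <- tolower(df[["Status"]])
  out <- data.frame(
    cnvr_id = df[["CNVR NO."]],
    chrom = normalize_chrom(df[["Chr"]]),
    start = as.numeric(df[["Start"]]), end = as.numeric(df[["End"]]),
    status = status, stringsAsFactors = FALSE)
  if ("Breed" %in% names(df)) out$breed <- df[["Breed"]]
  if ("Length (Kb)" %in% names(df)) out$length_kb <- df[["Length (Kb)"]]
  validate_intervals(out, path)
  out
}

#' Read a sample sheet
#'
#' @param path delimited file with columns `sample_id`, `generation`
#'   (F0/F1/F2), `breed`, and optionally `sex`.
#' @param sep separator (autodetected when NULL).
#' @export
read_samples <- function(path, sep = NULL) {
  df <- .read_delim_auto(path, sep)
  need <- c("sample_id", "generation", "breed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  if (any(!nzchar(df$generation)) || any(!nzchar(df$breed)))
    stop(path, ": generation and breed must be non-empty")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read a genotype matrix
#'
#' @param path tab-separated file, first column `snp_id`, remaining columns
#'   one per sample; entries in `AA`, `AB`, `BB` or a missing token.
#' @param missing_tokens values treated as missing (become NA).
#' @return character matrix, rows = SNPs (rownames = snp_id), cols = samples.
#' @export
read_genotypes <- function(path, missing_tokens = c("NN", "--", "NA", "")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m[m %in% missing_tokens] <- NA
  bad <- stats::na.omit(setdiff(unique(as.vector(m)), c("AA", "AB", "BB")))
  if (length(bad))
    stop(path, ": unknown genotype token(s): ", paste(bad, collapse = ", "))
  m
}

#' Read a long-format qPCR CT table
#'
#' @param path delimited file with columns `cnvr_id`, `sample_id`, `well`
#'   (`target` or `control`), `ct` (one row per replicate).
#' @param sep separator (autodetected when NULL).
#' @export
read_qpcr <- function(path, sep = NULL) {
  df <- .read_delim_auto(path, sep)
  need <- c("cnvr_id", "sample_id", "well", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$well %in% c("target", "control")))
    stop(path, ": well must be 'target' or 'control'")
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct) | df$ct <= 0))
    stop(path, ": CT values must be finite and positive")
  df
}

#' Validate a pipeline file against a schema
#'
#' Lightweight CLI-facing check: attempts to parse `path` under the named
#' schema and reports success or the first error.
#'
#' @param path file to check.
#' @param schema one of `calls`, `cnvrs`, `features`, `genotypes`,
#'   `samples`, `qpcr`.
#' @param ... passed to the underlying reader (e.g. `coords` for calls and
#'   features).
#' @return TRUE invisibly on success; otherwise stops.
#' @export
validate_file <- function(path, schema = c("calls", "cnvrs", "features",
                                           "genotypes", "samples", "qpcr"),
                          ...) {
  schema <- match.arg(schema)
  switch(schema,
    calls = read_cnv_calls(path, algorithm_id = "check", ...),
    cnvrs = read_cnvrs(path),
    features = read_features(path, ...),
    genotypes = read_genotypes(path),
    samples = read_samples(path),
    qpcr = read_qpcr(path))
  invisible(TRUE)
}
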