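## Mechanism annotation of merged SVs: local tandem expansion or
## contraction (SV sequence matches its immediate flank), transposable
## element insertion (match against a TE library), gene duplication
## (match against a CDS library).  Precedence TANDEM > TE > GENE.

no_label <- function(id) {
  data.frame(id = id, mechanism = "UNCLASSIFIED", best_hit = NA_character_,
             identity = NA_real_, coverage = NA_real_,
             stringsAsFactors = FALSE)
}

## best local alignment of `seq` against one subject: identity over the
## aligned columns and coverage of `seq`
local_hit <- function(seq, subject) {
  ## fast path: exact containment either way
  if (grepl(seq, subject, fixed = TRUE))
    return(c(identity = 1, coverage = 1))
  if (grepl(subject, seq, fixed = TRUE))
    return(c(identity = 1, coverage = nchar(subject) / nchar(seq)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(seq, subject, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 4, gapExtension = 1)
  ptxt <- as.character(Biostrings::pattern(pa))
  ncols <- nchar(ptxt)
  if (ncols == 0) return(c(identity = 0, coverage = 0))
  aligned_on_seq <- nchar(gsub("-", "", ptxt, fixed = TRUE))
  c(identity = Biostrings::nmatch(pa) / ncols,
    coverage = aligned_on_seq / nchar(seq))
}

#' Classify a deletion/insertion as a local tandem event
#'
#' The SV sequence is compared to the immediately flanking reference
#' sequence (windows of one SV length each side); a flank match at
#' identity >= `min_identity` over >= `min_coverage` of the SV length
#' labels the site TANDEM (an insertion is a tandem expansion, a
#' deletion a tandem contraction).
#'
#' @param site merged DEL/INS site row (with `seq`).
#' @param ref_genome reference `DNAStringSet`.
#' @param min_identity,min_coverage thresholds.
#' @return one-row label data.frame (`mechanism` is `"TANDEM"` or
#'   `"UNCLASSIFIED"`).
#' @export
classify_tandem <- function(site, ref_genome, min_identity = 0.8,
                            min_coverage = 0.8) {
  if (is.na(site$seq) || !nzchar(site$seq)) return(no_label(site$id))
  L <- nchar(site$seq)
  sz <- genome_sizes(ref_genome)[[site$ref_name]]
  left <- genome_subseq(ref_genome, site$ref_name,
                        max(0, site$ref_start - L), site$ref_start)
  right <- genome_subseq(ref_genome, site$ref_name, site$ref_end,
                         min(sz, site$ref_end + L))
  best <- c(identity = 0, coverage = 0); side <- NA_character_
  for (fl in c("left", "right")) {
    fseq <- if (fl == "left") left else right
    if (!nzchar(fseq)) next
    h <- local_hit(site$seq, fseq)
    if (h["identity"] >= min_identity && h["coverage"] >= min_coverage &&
        h["coverage"] > best["coverage"]) { best <- h; side <- fl }
  }
  if (is.na(side)) return(no_label(site$id))
  data.frame(id = site$id, mechanism = "TANDEM",
             best_hit = paste0("flank_", side),
             identity = unname(best["identity"]),
             coverage = unname(best["coverage"]), stringsAsFactors = FALSE)
}

classify_library <- function(site, library, label, min_identity = 0.8,
                             min_coverage = 0.5) {
  if (length(library) == 0L) stop("config error: empty library")
  if (is.na(site$seq) || !nzchar(site$seq)) return(no_label(site$id))
  best <- NULL
  for (nm in names(library)) {
    h <- local_hit(site$seq, as.character(library[[nm]]))
    if (h["identity"] < min_identity || h["coverage"] < min_coverage) next
    if (is.null(best) || h["coverage"] * h["identity"] >
        best$coverage * best$identity)
      best <- list(name = nm, identity = unname(h["identity"]),
                   coverage = unname(h["coverage"]))
  }
  if (is.null(best)) return(no_label(site$id))
  data.frame(id = site$id, mechanism = label, best_hit = best$name,
             identity = best$identity, coverage = best$coverage,
             stringsAsFactors = FALSE)
}

#' Classify an SV sequence as a transposable-element insertion
#'
#' Local alignment of the SV sequence against each library entry; TE
#' when the best hit covers >= `min_coverage` of the SV length at
#' identity >= `min_identity`.  The best family is reported.
#'
#' @param site merged site row with `seq`.
#' @param te_library named `DNAStringSet` of intact TE sequences.
#' @param min_identity,min_coverage thresholds.
#' @return one-row label data.frame.
#' @export
classify_te <- function(site, te_library, min_identity = 0.8,
                        min_coverage = 0.5) {
  classify_library(site, te_library, "TE", min_identity, min_coverage)
}

#' Classify an SV sequence as a gene (CDS) duplication
#'
#' @param site merged site row with `seq`.
#' @param cds_library named `DNAStringSet` of full-length CDS.
#' @param min_identity,min_coverage thresholds.
#' @return one-row label data.frame.
#' @export
classify_gene <- function(site, cds_library, min_identity = 0.8,
                          min_coverage = 0.5) {
  classify_library(site, cds_library, "GENE", min_identity, min_coverage)
}

#' Annotate merged sites with formation mechanisms
#'
#' Runs tandem / TE / gene classification for every DEL and INS site and
#' combines the passing labels with precedence TANDEM > TE > GENE.
#'
#' @param sites merged site table.
#' @param ref_genome reference assembly.
#' @param te_library,cds_library optional named `DNAStringSet`s.
#' @param min_identity identity threshold shared by the classifiers.
#' @param tandem_coverage,library_coverage coverage thresholds.
#' @return data.frame with `id`, `mechanism` (primary), `all`
#'   (comma-separated passing labels), `best_hit`, `identity`,
#'   `coverage`.
#' @export
annotate_mechanisms <- function(sites, ref_genome, te_library = NULL,
                                cds_library = NULL, min_identity = 0.8,
                                tandem_coverage = 0.8,
                                library_coverage = 0.5) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    labels <- list()
    if (site$svtype %in% c("DEL", "INS") && !is.na(site$seq)) {
      t1 <- classify_tandem(site, ref_genome, min_identity, tandem_coverage)
      if (t1$mechanism != "UNCLASSIFIED") labels$TANDEM <- t1
      if (!is.null(te_library)) {
        t2 <- classify_te(site, te_library, min_identity, library_coverage)
        if (t2$mechanism != "UNCLASSIFIED") labels$TE <- t2
      }
      if (!is.null(cds_library)) {
        t3 <- classify_gene(site, cds_library, min_identity,
                            library_coverage)
        if (t3$mechanism != "UNCLASSIFIED") labels$GENE <- t3
      }
    }
    if (!length(labels)) {
      lab <- no_label(site$id)
      lab$all <- ""
      out[[i]] <- lab
      next
    }
    prim <- labels[[intersect(c("TANDEM", "TE", "GENE"),
                              names(labels))[1]]]
    prim$all <- paste(intersect(c("TANDEM", "TE", "GENE"), names(labels)),
                      collapse = ",")
    out[[i]] <- prim
  }
  do.call(rbind, out) %||%
    data.frame(id = character(0), mechanism = character(0),
               best_hit = character(0), identity = numeric(0),
               coverage = numeric(0), all = character(0))
}
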