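#' Curated demonstration taxonomy for the synthetic reference database
#'
#' A small table of UK vertebrates (plus the human contaminant and an exotic
#' cichlid used as positive-control spike) with full seven-rank lineages and a
#' coarse habitat classification. `generate_reference_db()` draws its lineages
#' from this table, so simulated databases contain multiple congeneric species
#' (e.g. *Apodemus*, *Sorex*, *Anas*, *Emberiza*) and majority-LCA votes are
#' non-trivial.
#'
#' @return A tibble with columns `class`, `order`, `family`, `genus`,
#'   `species` and `habitat_class` (one of woodland, open, aquatic, none).
#' @export
demo_taxonomy <- function() {
  tribble_row <- function(cl, or, fa, ge, sp, hab) {
    tibble(class = cl, order = or, family = fa, genus = ge, species = sp,
           habitat_class = hab)
  }
  rows <- list(
    # candidate hosts first, then contaminant and positive control, then prey:
    # the head of this table is always present in small simulated databases.
    tribble_row("Mammalia", "Carnivora", "Canidae", "Vulpes", "Vulpes vulpes", "open"),
    tribble_row("Mammalia", "Carnivora", "Mustelidae", "Martes", "Martes martes", "woodland"),
    tribble_row("Mammalia", "Primates", "Hominidae", "Homo", "Homo sapiens", "none"),
    tribble_row("Actinopterygii", "Cichliformes", "Cichlidae", "Maylandia", "Maylandia zebra", "none"),
    tribble_row("Mammalia", "Rodentia", "Cricetidae", "Microtus", "Microtus agrestis", "open"),
    tribble_row("Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus sylvaticus", "woodland"),
    tribble_row("Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus flavicollis", "woodland"),
    tribble_row("Mammalia", "Rodentia", "Cricetidae", "Myodes", "Myodes glareolus", "woodland"),
    tribble_row("Mammalia", "Eulipotyphla", "Soricidae", "Sorex", "Sorex araneus", "open"),
    tribble_row("Mammalia", "Eulipotyphla", "Soricidae", "Sorex", "Sorex minutus", "open"),
    tribble_row("Amphibia", "Anura", "Ranidae", "Rana", "Rana temporaria", "aquatic"),
    tribble_row("Mammalia", "Artiodactyla", "Cervidae", "Cervus", "Cervus elaphus", "open"),
    tribble_row("Mammalia", "Lagomorpha", "Leporidae", "Oryctolagus", "Oryctolagus cuniculus", "open"),
    tribble_row("Aves", "Galliformes", "Phasianidae", "Phasianus", "Phasianus colchicus", "open"),
    tribble_row("Aves", "Galliformes", "Phasianidae", "Lagopus", "Lagopus lagopus", "open"),
    tribble_row("Aves", "Passeriformes", "Fringillidae", "Fringilla", "Fringilla coelebs", "woodland"),
    tribble_row("Aves", "Passeriformes", "Emberizidae", "Emberiza", "Emberiza citrinella", "open"),
    tribble_row("Aves", "Passeriformes", "Emberizidae", "Emberiza", "Emberiza schoeniclus", "open"),
    tribble_row("Aves", "Anseriformes", "Anatidae", "Anas", "Anas platyrhynchos", "aquatic"),
    tribble_row("Aves", "Anseriformes", "Anatidae", "Anas", "Anas crecca", "aquatic"),
    tribble_row("Aves", "Columbiformes", "Columbidae", "Columba", "Columba palumbus", "woodland"),
    tribble_row("Reptilia", "Squamata", "Lacertidae", "Zootoca", "Zootoca vivipara", "open"),
    tribble_row("Aves", "Charadriiformes", "Scolopacidae", "Scolopax", "Scolopax rusticola", "woodland"),
    tribble_row("Mammalia", "Lagomorpha", "Leporidae", "Lepus", "Lepus timidus", "open"),
    tribble_row("Mammalia", "Artiodactyla", "Cervidae", "Capreolus", "Capreolus capreolus", "woodland"),
    tribble_row("Mammalia", "Rodentia", "Sciuridae", "Sciurus", "Sciurus vulgaris", "woodland"),
    tribble_row("Mammalia", "Carnivora", "Canidae", "Canis", "Canis familiaris", "none"),
    tribble_row("Aves", "Passeriformes", "Turdidae", "Turdus", "Turdus merula", "woodland"),
    tribble_row("Aves", "Passeriformes", "Troglodytidae", "Troglodytes", "Troglodytes troglodytes", "woodland"),
    tribble_row("Aves", "Passeriformes", "Motacillidae", "Anthus", "Anthus pratensis", "open"),
    tribble_row("Aves", "Charadriiformes", "Charadriidae", "Pluvialis", "Pluvialis apricaria", "open"),
    tribble_row("Aves", "Charadriiformes", "Scolopacidae", "Numenius", "Numenius arquata", "open"),
    tribble_row("Amphibia", "Anura", "Bufonidae", "Bufo", "Bufo bufo", "aquatic"),
    tribble_row("Actinopterygii", "Salmoniformes", "Salmonidae", "Salmo", "Salmo trutta", "aquatic"),
    tribble_row("Actinopterygii", "Salmoniformes", "Salmonidae", "Salmo", "Salmo salar", "aquatic"),
    tribble_row("Aves", "Strigiformes", "Strigidae", "Asio", "Asio flammeus", "open"),
    tribble_row("Mammalia", "Rodentia", "Cricetidae", "Arvicola", "Arvicola amphibius", "aquatic"),
    tribble_row("Aves", "Accipitriformes", "Accipitridae", "Accipiter", "Accipiter nisus", "woodland"),
    tribble_row("Aves", "Passeriformes", "Paridae", "Parus", "Parus major", "woodland"),
    tribble_row("Mammalia", "Eulipotyphla", "Erinaceidae", "Erinaceus", "Erinaceus europaeus", "open")
  )
  base <- dplyr::bind_rows(rows)
  base$domain <- "Eukaryota"
  base$phylum <- "Chordata"
  base[, c(TAX_RANKS, "habitat_class")]
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

#' Pairwise percent identity between nucleotide sequences
#'
#' Identity is computed from the Levenshtein edit distance as
#' `100 * (1 - d / max(nchar))`, i.e. a global-alignment identity where every
#' substitution or indel counts once against the longer sequence.
#'
#' @param a,b Character vectors of sequences; identities are computed for all
#'   pairs (rows of `a`, columns of `b`).
#' @return Numeric matrix of percent identities in `[0, 100]`.
#' @export
sequence_identity <- function(a, b) {
  d <- adist(a, b)
  len <- outer(nchar(a), nchar(b), pmax)
  100 * (1 - d / len)
}

#' Generate a synthetic curated reference database
#'
#' Builds `n_species` reference records with full seven-rank lineages drawn
#' from [demo_taxonomy()] (extra species beyond the curated table are placed
#' into existing genera, so some genera hold several species and majority-LCA
#' votes can legitimately stop at genus level). Amplicon-length sequences are
#' drawn at random and re-drawn until every between-species percent identity
#' is below `identity_threshold - identity_margin`, so no simulated read can
#' be confused between reference species at the species-assignment threshold.
#'
#' @param n_species Number of reference species (>= 2).
#' @param seed Integer seed; the same seed reproduces the database exactly.
#' @param seq_length Amplicon length in nucleotides (default 97, the 12S
#'   vertebrate fragment length this pipeline targets).
#' @param identity_threshold Species-assignment identity threshold in percent
#'   (default 98, matching the hit-filter default).
#' @param identity_margin Safety margin in percent (default 4): pairwise
#'   reference identity is kept below `identity_threshold - identity_margin`.
#' @return A tibble (one row per species) with columns `taxon_id`, the seven
#'   rank columns, `habitat_class` and `sequence`.
#' @export
#' @examples
#' db <- generate_reference_db(6, seed = 1)
#' db$taxon_id
generate_reference_db <- function(n_species, seed, seq_length = 97,
                                  identity_threshold = 98,
                                  identity_margin = 4) {
  if (!is.numeric(n_species) || length(n_species) != 1 || n_species < 2) {
    abort("`n_species` must be a single integer >= 2.")
  }
  n_species <- as.integer(n_species)
  base <- demo_taxonomy()
  with_seed(derive_seed(seed, 1L), {
    if (n_species <= nrow(base)) {
      lineages <- base[seq_len(n_species), ]
    } else {
      extra_n <- n_species - nrow(base)
      donor <- base[1 + (seq_len(extra_n) - 1) %% nrow(base), ]
      donor$species <- sprintf("%s simulatus%02d", donor$genus, seq_len(extra_n))
      lineages <- dplyr::bind_rows(base, donor)
    }
    max_ident <- identity_threshold - identity_margin
    seqs <- random_dna(n_species, seq_length)
    # reject-and-redraw until all between-species identities clear the margin;
    # random sequences of ~100 nt essentially always do in one pass
    for (attempt in seq_len(50)) {
      idm <- sequence_identity(seqs, seqs)
      diag(idm) <- 0
      bad <- which(apply(idm, 1, max) >= max_ident)
      if (length(bad) == 0) break
      if (attempt == 50) {
        abort("could not draw reference sequences below the identity margin")
      }
      seqs[bad] <- random_dna(length(bad), seq_length)
    }
    out <- lineages
    out$taxon_id <- sprintf("t%03d", seq_len(n_species))
    out$sequence <- seqs
    out[, c("taxon_id", TAX_RANKS, "habitat_class", "sequence")]
  })
}

#' Write / read a reference database as FASTA plus a lineage table
#'
#' The FASTA records are named by `taxon_id`; the lineage table is
#' tab-separated with columns `taxon_id`, the seven ranks and
#' `habitat_class`.
#'
#' @param db Reference tibble from [generate_reference_db()].
#' @param fasta_path,lineage_path Output file paths.
#' @return `write_reference_db()` returns the paths invisibly;
#'   `read_lineage_table()` returns the lineage tibble.
#' @export
write_reference_db <- function(db, fasta_path, lineage_path) {
  assert_cols(db, c("taxon_id", TAX_RANKS, "habitat_class", "sequence"))
  seqs <- Biostrings::DNAStringSet(setNames(db$sequence, db$taxon_id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  readr::write_tsv(db[, c("taxon_id", TAX_RANKS, "habitat_class")], lineage_path)
  invisible(c(fasta = fasta_path, lineage = lineage_path))
}

#' @rdname write_reference_db
#' @param path Path of a lineage table written by [write_reference_db()].
#' @export
read_lineage_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path FASTA file path.
#' @return Tibble with columns `name` and `sequence`.
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = names(x), sequence = as.character(x))
}
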