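# Planted-motif synthetic DTI benchmark. An interaction is defined by a
# ground-truth rule: a pair is positive when the protein carries a short
# planted residue motif AND the drug carries a reactive substructure motif;
# labels are then flipped with probability `rho` to emulate assay noise. The
# planted protein motif positions are recorded as binding-site annotations,
# giving the attention-site analysis a known ground truth.

# Curated base molecules: small valid SMILES whose final atom has free
# valence, so fragments and the drug motif can be appended by concatenation.
DRUG_BASE <- c(
  "CCO", "CCN", "CCC", "CCCC", "COC", "CNC", "CCOC", "CCNC", "CCCN", "CCCO",
  "OCCO", "NCCN", "OCCN", "CC(C)C", "CC(C)O", "CC(C)N", "CC(=O)C", "CC(=O)OC",
  "CC(=O)N", "CC(N)C", "CN(C)C", "CC(O)C", "CCS", "CSC", "CSCC", "CCOCC",
  "CCNCC", "CC=CC", "CC(=C)C", "CC=CO", "CC=CN", "CCC(C)O", "CCC(C)N",
  "CCC(=O)C", "OCC(C)C", "NCC(C)C", "CC(C)CO", "CC(C)CN", "CCC(C)C",
  "CCCC(C)C", "c1ccccc1C", "c1ccccc1CC", "c1ccccc1O", "c1ccccc1N",
  "C1CCCCC1C", "C1CCCC1C", "C1CCOC1C", "C1CCNC1C", "OC(=O)CC", "CC(C)(C)C"
)

# chain fragments used to extend a base molecule (same concatenation-safe
# property as DRUG_BASE)
DRUG_FRAGMENTS <- c(
  "CC", "CCC", "CO", "CCO", "CN", "CCN", "COC", "CNC",
  "C(C)C", "C(=O)C", "C(N)C", "CC(C)O", "CC(N)C", "OCC", "NCC", "CC(=O)C"
)

#' Specification of a synthetic planted-motif DTI benchmark
#'
#' @param n_pairs Total number of drug-target pairs (default 2000).
#' @param rho Label-flip noise probability in `[0, 0.5)` (default 0.05).
#' @param imbalance Negative:positive ratio of the generated pairs (default 1,
#'   i.e. balanced; 20 emulates a heavily negative-skewed benchmark).
#' @param protein_motif Planted residue motif (default 8 residues).
#' @param drug_motif Planted SMILES substructure, appended to rule-positive
#'   drugs (default the isocyanate group `"N=C=O"`).
#' @param protein_len Protein length range in residues (default 80-120).
#' @param drug_len Drug length range in SMILES characters (default 8-40).
#' @param drug_base,drug_fragments Curated molecule list and extension
#'   fragments drugs are assembled from.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pairs = 2000L, rho = 0.05, imbalance = 1,
                           protein_motif = "HKWCYFDE", drug_motif = "N=C=O",
                           protein_len = c(80L, 120L), drug_len = c(8L, 40L),
                           drug_base = DRUG_BASE,
                           drug_fragments = DRUG_FRAGMENTS) {
  stopifnot(n_pairs >= 2L, rho >= 0, rho < 0.5, imbalance > 0,
            nchar(protein_motif) >= 1L,
            all(strsplit(protein_motif, "")[[1]] %in% AA_STANDARD),
            length(drug_base) >= 2L, length(drug_fragments) >= 2L,
            drug_len[1] >= 1L, drug_len[2] >= drug_len[1],
            protein_len[2] >= protein_len[1])
  if (nchar(protein_motif) > protein_len[1])
    stop("protein motif longer than the minimum protein length")
  if (nchar(drug_motif) + min(nchar(drug_base)) > drug_len[2])
    stop("drug motif does not fit the maximum drug length")
  if (!smiles_is_valid(drug_motif)) stop("drug motif is not a valid SMILES fragment")
  structure(list(
    n_pairs = as.integer(n_pairs), rho = rho, imbalance = imbalance,
    protein_motif = protein_motif, drug_motif = drug_motif,
    protein_len = as.integer(protein_len), drug_len = as.integer(drug_len),
    drug_base = drug_base, drug_fragments = drug_fragments
  ), class = "synthetic_spec")
}

random_protein <- function(len_range, motif, plant) {
  L <- sample(seq(len_range[1], len_range[2]), 1L)
  aa <- sample(AA_STANDARD, L, replace = TRUE)
  repeat {
    seq_str <- paste(aa, collapse = "")
    if (plant) break
    # a decoy protein must not contain the motif by chance
    if (!grepl(motif, seq_str, fixed = TRUE)) break
    aa <- sample(AA_STANDARD, L, replace = TRUE)
  }
  if (!plant) return(list(sequence = seq_str, sites = integer(0)))
  m <- nchar(motif)
  start <- sample(seq_len(L - m + 1L), 1L)
  aa[start:(start + m - 1L)] <- strsplit(motif, "")[[1]]
  list(sequence = paste(aa, collapse = ""),
       sites = seq.int(start, start + m - 1L))
}

random_drug <- function(spec, plant) {
  budget <- spec$drug_len[2] - if (plant) nchar(spec$drug_motif) else 0L
  repeat {
    smi <- sample(spec$drug_base, 1L)
    while (nchar(smi) < spec$drug_len[1] &&
           nchar(smi) + min(nchar(spec$drug_fragments)) <= budget) {
      frag <- sample(spec$drug_fragments, 1L)
      if (nchar(smi) + nchar(frag) > budget) next
      smi <- paste0(smi, frag)
    }
    if (plant) smi <- paste0(smi, spec$drug_motif)
    if (!plant && grepl(spec$drug_motif, smi, fixed = TRUE)) next
    if (nchar(smi) > spec$drug_len[2]) next
    if (smiles_is_valid(smi)) return(smi)
  }
}

#' Generate a synthetic planted-motif DTI dataset
#'
#' Rule-positive pairs receive both motifs; rule-negative pairs miss the
#' protein motif, the drug motif, or both (uniformly among the three cases),
#' so neither motif alone determines the label. Labels are flipped with
#' probability `rho` after the rule is applied. `binding_sites` records the
#' planted motif's residue positions for every motif-bearing protein.
#'
#' @param spec A [synthetic_spec()].
#' @param seed RNG seed; the dataset is fully reproducible from it.
#' @return DTI data frame with columns `smiles`, `sequence`, `label`,
#'   `rule_label` (pre-noise truth) and `binding_sites`.
#' @export
synthetic_dataset <- function(spec = synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_pairs
  n_pos <- max(1L, round(n / (1 + spec$imbalance)))
  rule <- as.integer(seq_len(n) <= n_pos)
  # among rule-negatives: 1 = neither motif, 2 = protein only, 3 = drug only
  neg_case <- sample(1:3, n, replace = TRUE)
  smiles <- character(n); sequence <- character(n)
  sites <- character(n)
  for (i in seq_len(n)) {
    prot_has <- rule[i] == 1L || neg_case[i] == 2L
    drug_has <- rule[i] == 1L || neg_case[i] == 3L
    pr <- random_protein(spec$protein_len, spec$protein_motif, prot_has)
    sequence[i] <- pr$sequence
    sites[i] <- if (length(pr$sites)) paste(pr$sites, collapse = ",") else NA_character_
    smiles[i] <- random_drug(spec, drug_has)
  }
  flip <- stats::runif(n) < spec$rho
  label <- ifelse(flip, 1L - rule, rule)
  out <- data.frame(smiles = smiles, sequence = sequence, label = label,
                    rule_label = rule, binding_sites = sites,
                    stringsAsFactors = FALSE)
  out[sample.int(n), , drop = FALSE]
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d pairs, rho %.2f, imbalance %.1f:1\n  protein motif %s | drug motif %s | protein %d-%d aa | drug %d-%d chars\n",
    x$n_pairs, x$rho, x$imbalance, x$protein_motif, x$drug_motif,
    x$protein_len[1], x$protein_len[2], x$drug_len[1], x$drug_len[2]))
  invisible(x)
}
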