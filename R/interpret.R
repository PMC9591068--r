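# Attention-site statistical analysis: expand token-level cross-attention
# weights to residue x atom resolution, pick the top-k sites, count how many
# fall on experimentally annotated binding residues (the consistency number),
# and judge that count against a permutation null in which binding residues
# are placed uniformly at random (matched set sizes). All coordinates in
# reports are 1-based.

#' Expand a token-level attention map to residue x atom resolution
#'
#' Each token-pair weight is broadcast to every (residue, atom) cell covered
#' by the two tokens' character spans; PAD positions are already excluded
#' because spans only cover the encoded prefix.
#'
#' @param weights Head-averaged attention matrix (protein tokens x drug
#'   tokens), e.g. from [attention_map()].
#' @param prot_spans,drug_spans Two-column matrices (`start`, `width`) giving
#'   each token's 1-based character span, as produced by [model_encode()].
#' @return Numeric matrix (protein residues x drug characters) of class
#'   `attention_sites_map`.
#' @export
expand_attention <- function(weights, prot_spans, drug_spans) {
  if (nrow(weights) != nrow(prot_spans) || ncol(weights) != nrow(drug_spans))
    stop("token spans inconsistent with attention matrix dimensions")
  rrep <- rep(seq_len(nrow(weights)), times = prot_spans[, "width"])
  crep <- rep(seq_len(ncol(weights)), times = drug_spans[, "width"])
  structure(weights[rrep, crep, drop = FALSE], class = "attention_sites_map")
}

#' Top-k attention sites of an expanded map
#'
#' Cells are ranked by weight, descending; ties break by ascending (residue,
#' atom). If `k` exceeds the cell count, all cells are returned with a
#' warning.
#'
#' @param map Expanded residue x atom attention matrix.
#' @param k Number of sites (default 30).
#' @return Data frame `residue`, `atom`, `weight`, ordered by rank.
#' @export
top_sites <- function(map, k = 30L) {
  stopifnot(k >= 1L)
  n <- length(map)
  if (k > n) {
    warning("k exceeds the number of attention cells; returning all ", n)
    k <- n
  }
  res <- as.vector(row(map)); atm <- as.vector(col(map)); w <- as.vector(map)
  ord <- order(-w, res, atm)[seq_len(k)]
  data.frame(residue = res[ord], atom = atm[ord], weight = w[ord])
}

#' Consistency number: attention sites on annotated binding residues
#'
#' @param sites Data frame from [top_sites()].
#' @param binding Integer vector of 1-based binding residue positions.
#' @return Integer count of sites whose residue is a binding residue.
#' @export
consistency_number <- function(sites, binding) {
  sum(sites$residue %in% binding)
}

#' Permutation null profile of consistency numbers
#'
#' For each iteration and each DTI, binding residues are re-placed uniformly
#' at random without replacement along the protein (matching the annotated
#' set size), the consistency number with the fixed top-k sites is counted,
#' and the per-iteration mean over DTIs is recorded.
#'
#' @param sites_list List of [top_sites()] data frames, one per DTI.
#' @param protein_lengths Integer vector of true (encoded) protein lengths.
#' @param binding_sizes Integer vector of annotated binding-set sizes.
#' @param iterations Number of permutation iterations (default 10000).
#' @param seed RNG seed.
#' @return Object of class `null_profile`: `draws` (per-iteration means),
#'   `mean`, `sd`.
#' @export
null_profile <- function(sites_list, protein_lengths, binding_sizes,
                         iterations = 10000L, seed = 1L) {
  stopifnot(iterations >= 1L,
            length(sites_list) == length(protein_lengths),
            length(protein_lengths) == length(binding_sizes))
  if (any(binding_sizes > protein_lengths))
    stop("binding-set size exceeds protein length")
  set.seed(seed)
  n <- length(sites_list)
  total <- numeric(iterations)
  for (i in seq_len(n)) {
    L <- protein_lengths[i]; b <- binding_sizes[i]
    cnt <- tabulate(sites_list[[i]]$residue, nbins = L)
    if (b == L) {
      total <- total + sum(cnt)
    } else {
      total <- total + vapply(seq_len(iterations),
                              function(j) sum(cnt[sample.int(L, b)]), numeric(1))
    }
  }
  draws <- total / n
  structure(list(draws = draws, mean = mean(draws), sd = stats::sd(draws)),
            class = "null_profile")
}

#' @export
print.null_profile <- function(x, ...) {
  cat(sprintf("<null_profile> %d iterations: mean %.4f, sd %.4f\n",
              length(x$draws), x$mean, x$sd))
  invisible(x)
}

#' z-score of an observed consistency mean against a null profile
#'
#' @param observed_mean Observed mean consistency number over DTIs.
#' @param profile A `null_profile`, or a list with `mean` and `sd`.
#' @return `(observed_mean - mean) / sd`.
#' @export
z_score <- function(observed_mean, profile) {
  if (is.null(profile$sd) || profile$sd <= 0) stop("null profile has zero spread")
  (observed_mean - profile$mean) / profile$sd
}

# Assemble the per-DTI inputs (expanded maps, binding sets, lengths) for the
# annotated samples of a dataset. Binding residues beyond the encoded protein
# prefix are excluded (and counted).
collect_attention_maps <- function(checkpoint, dataset, rows = NULL) {
  model <- checkpoint$model
  if (is.null(rows)) {
    rows <- which(!is.na(dataset$binding_sites) & nzchar(dataset$binding_sites))
  }
  if (length(rows) == 0L) stop("no samples with binding-site annotations")
  enc <- model_encode(model, dataset$smiles[rows], dataset$sequence[rows])
  maps <- vector("list", length(rows))
  binding <- vector("list", length(rows))
  lengths <- integer(length(rows))
  excluded <- 0L
  for (j in seq_along(rows)) {
    am <- attention_map(model, enc, j)
    maps[[j]] <- expand_attention(am$weights, am$prot_spans, am$drug_spans)
    L <- nrow(maps[[j]])
    bs <- parse_positions(dataset$binding_sites[rows[j]])
    keep <- bs[bs >= 1L & bs <= L]
    excluded <- excluded + (length(bs) - length(keep))
    binding[[j]] <- keep
    lengths[j] <- L
  }
  if (excluded > 0L)
    message(excluded, " binding residue(s) beyond the encoded protein prefix excluded")
  list(maps = maps, binding = binding, lengths = lengths, rows = rows)
}

#' Full attention-site analysis of a trained model
#'
#' Computes expanded attention maps for all annotated samples, the observed
#' mean consistency number of the top-k sites, the permutation null profile,
#' and the resulting z-score.
#'
#' @param checkpoint A trained `dti_checkpoint` (protein-query architecture).
#' @param dataset DTI data frame with a `binding_sites` column.
#' @param rows Row indices to analyse (default: all annotated rows).
#' @param k Number of top attention sites (default 30).
#' @param iterations Permutation iterations (default 10000).
#' @param seed RNG seed for the permutation null.
#' @return Object of class `attention_analysis`: observed per-DTI consistency
#'   numbers and their mean, the `null_profile`, the z-score, and the site
#'   tables.
#' @export
attention_site_analysis <- function(checkpoint, dataset, rows = NULL, k = 30L,
                                    iterations = 10000L, seed = 1L) {
  cm <- collect_attention_maps(checkpoint, dataset, rows)
  sites <- lapply(cm$maps, top_sites, k = k)
  obs <- mapply(consistency_number, sites, cm$binding)
  prof <- null_profile(sites, cm$lengths,
                       vapply(cm$binding, length, 0L), iterations, seed)
  structure(list(
    consistency = obs, observed_mean = mean(obs), null = prof,
    z = z_score(mean(obs), prof), sites = sites, binding = cm$binding,
    protein_lengths = cm$lengths, k = k, rows = cm$rows, maps = cm$maps
  ), class = "attention_analysis")
}

#' @export
print.attention_analysis <- function(x, ...) {
  cat(sprintf(
    "<attention_analysis> %d DTIs, top-%d sites\n  observed consistency %.3f | null %.3f (sd %.3f) | z = %.3f\n",
    length(x$consistency), x$k, x$observed_mean, x$null$mean, x$null$sd, x$z))
  invisible(x)
}

#' Sensitivity of the analysis to the number of top sites
#'
#' Repeats the consistency/z computation for each `k`, reusing the expanded
#' maps.
#'
#' @param analysis An `attention_analysis` (its maps and annotations are
#'   reused).
#' @param k_values Integer vector of site counts.
#' @param iterations,seed Permutation controls.
#' @return Data frame `k`, `consistency`, `z`, ordered by `k`.
#' @export
topk_sensitivity <- function(analysis, k_values = c(10L, 20L, 30L, 40L, 50L),
                             iterations = 10000L, seed = 1L) {
  stopifnot(all(k_values >= 1L))
  k_values <- sort(k_values)
  out <- lapply(k_values, function(k) {
    sites <- lapply(analysis$maps, top_sites, k = k)
    obs <- mean(mapply(consistency_number, sites, analysis$binding))
    prof <- null_profile(sites, analysis$protein_lengths,
                         vapply(analysis$binding, length, 0L), iterations, seed)
    data.frame(k = k, consistency = obs, z = z_score(obs, prof))
  })
  do.call(rbind, out)
}

shift_sites <- function(sites, shift, L) {
  s <- sites
  s$residue <- s$residue + shift
  s[s$residue >= 1L & s$residue <= L, , drop = FALSE]
}

#' Effect of shifting attention sites along the protein axis
#'
#' Each site's residue coordinate is offset by the shift before consistency
#' counting (sites shifted outside the protein are dropped); shift 0
#' reproduces the base analysis. The null profile is rebuilt per shift since
#' boundary drops change the site tables.
#'
#' @param analysis An `attention_analysis`.
#' @param shifts Integer offsets (default -2..2).
#' @param iterations,seed Permutation controls.
#' @return Data frame `shift`, `consistency`, `z`.
#' @export
shift_analysis <- function(analysis, shifts = -2:2, iterations = 10000L,
                           seed = 1L) {
  out <- lapply(shifts, function(sh) {
    sites <- mapply(shift_sites, analysis$sites, sh, analysis$protein_lengths,
                    SIMPLIFY = FALSE)
    obs <- mean(mapply(consistency_number, sites, analysis$binding))
    prof <- null_profile(sites, analysis$protein_lengths,
                         vapply(analysis$binding, length, 0L), iterations, seed)
    data.frame(shift = sh, consistency = obs, z = z_score(obs, prof))
  })
  do.call(rbind, out)
}

# parse "12,15,20" (or ; separated) into an integer vector
parse_positions <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(gsub(";", ",", x), ",", fixed = TRUE)[[1]])
}
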