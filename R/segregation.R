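# Family-based segregation test under Mendelian transmission with complete
# penetrance: affected members must carry at least one alternate allele and
# unaffected members none; members with another diagnosis or unknown
# phenotype impose no constraint; ungenotyped members are marginalised.
#
# Founder genotypes are independent Hardy-Weinberg draws at the population
# alternate-allele frequency q; each child allele is an independent fair
# draw from each parent. A parent absent from the pedigree contributes a
# population allele (equivalent to marginalising an implicit unconstrained
# founder).
#
# Two exact evaluation paths are provided: brute-force enumeration over all
# genotype configurations (default up to 12 members) and sum-product
# variable elimination ("peeling") for larger pedigrees. Both carry a log
# scale factor so probabilities never underflow.

hwe_prior <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# P(child dosage | father dosage, mother dosage):
# convolution of one Bernoulli(g_f/2) and one Bernoulli(g_m/2) allele draw.
transmission_array <- function() {
  T <- array(0, dim = c(3, 3, 3))
  for (gf in 0:2) for (gm in 0:2) {
    pf <- gf / 2; pm <- gm / 2
    T[1, gf + 1, gm + 1] <- (1 - pf) * (1 - pm)
    T[2, gf + 1, gm + 1] <- pf * (1 - pm) + (1 - pf) * pm
    T[3, gf + 1, gm + 1] <- pf * pm
  }
  T
}

# Normalise a family into an internal pedigree: implicit founders are
# materialised for children listing only one parent, so every non-founder
# has two in-pedigree parents.
build_pedigree <- function(fam) {
  fam <- fam[, c("member_id", "father_id", "mother_id", "phenotype"), drop = FALSE]
  known <- fam$member_id
  extra <- list()
  for (i in seq_len(nrow(fam))) {
    has_f <- !is.na(fam$father_id[i]); has_m <- !is.na(fam$mother_id[i])
    if (has_f && !(fam$father_id[i] %in% known)) {
      stop("father ", fam$father_id[i], " not in family")
    }
    if (has_m && !(fam$mother_id[i] %in% known)) {
      stop("mother ", fam$mother_id[i], " not in family")
    }
    if (xor(has_f, has_m)) {
      ph <- paste0(".implicit_parent_of_", fam$member_id[i])
      extra[[length(extra) + 1]] <- data.frame(
        member_id = ph, father_id = NA_character_, mother_id = NA_character_,
        phenotype = "unknown", stringsAsFactors = FALSE
      )
      if (!has_f) fam$father_id[i] <- ph else fam$mother_id[i] <- ph
    }
  }
  if (length(extra) > 0) fam <- rbind(fam, do.call(rbind, extra))
  # topological order (founders first); also detects cycles
  n <- nrow(fam)
  placed <- rep(FALSE, n)
  order_ix <- integer(0)
  repeat {
    ready <- which(!placed & vapply(seq_len(n), function(i) {
      f <- fam$father_id[i]; m <- fam$mother_id[i]
      (is.na(f) || placed[match(f, fam$member_id)]) &&
        (is.na(m) || placed[match(m, fam$member_id)])
    }, logical(1)))
    if (length(ready) == 0) break
    placed[ready] <- TRUE
    order_ix <- c(order_ix, ready)
  }
  if (!all(placed)) stop("pedigree contains a cycle")
  fam <- fam[order_ix, , drop = FALSE]
  rownames(fam) <- NULL
  fam
}

constraint_vector <- function(phenotype) {
  switch(phenotype,
    affected = c(0, 1, 1),
    unaffected = c(1, 0, 0),
    c(1, 1, 1)
  )
}

#' Per-family segregation probability
#'
#' Probability, under Mendelian inheritance with founders drawn at
#' Hardy-Weinberg proportions with alternate-allele frequency `q`, that
#' every affected family member carries at least one alternate allele and
#' every unaffected member carries none. Members with phenotype
#' `other_diagnosis` or `unknown` are unconstrained.
#'
#' @param fam A family data.frame with columns `member_id`, `father_id`,
#'   `mother_id`, `phenotype`.
#' @param q Founder alternate-allele frequency in `[0, 1]`.
#' @param method `"auto"` (enumeration up to `enumerate_limit` members, then
#'   peeling), `"enumerate"`, or `"peeling"`.
#' @param observed Optional named integer vector of observed dosages (0/1/2);
#'   named members are clamped to their genotypes instead of their
#'   phenotype-derived constraint. The default (phenotype constraints only)
#'   is the segregation-test reading.
#' @param condition_on_presence If `TRUE`, returns the probability
#'   conditional on the variant being present in at least one founder
#'   genome. Requires at least one affected member (so the event implies
#'   presence).
#' @param enumerate_limit Member count above which `"auto"` switches to
#'   peeling.
#' @return The segregation probability.
#' @export
family_segregation_prob <- function(fam, q,
                                    method = c("auto", "enumerate", "peeling"),
                                    observed = NULL,
                                    condition_on_presence = FALSE,
                                    enumerate_limit = 12) {
  method <- match.arg(method)
  if (!is.numeric(q) || q < 0 || q > 1) stop("q must be in [0, 1]")
  ped <- build_pedigree(fam)
  n <- nrow(ped)
  cons <- lapply(ped$phenotype, constraint_vector)
  names(cons) <- ped$member_id
  if (!is.null(observed)) {
    for (id in names(observed)) {
      if (!is.na(observed[[id]]) && id %in% ped$member_id) {
        v <- rep(0, 3)
        v[observed[[id]] + 1] <- 1
        cons[[id]] <- v
      }
    }
  }
  p <- if (method == "enumerate" || (method == "auto" && n <= enumerate_limit)) {
    seg_prob_enumerate(ped, q, cons)
  } else {
    seg_prob_peeling(ped, q, cons)
  }
  p <- min(max(p, 0), 1)  # guard rounding at the boundaries
  if (condition_on_presence) {
    if (!any(ped$phenotype == "affected")) {
      stop("conditioning on presence requires at least one affected member")
    }
    n_founders <- sum(is.na(ped$father_id) & is.na(ped$mother_id))
    p_present <- 1 - (1 - q)^(2 * n_founders)
    if (p_present == 0) return(0)
    p <- p / p_present
  }
  p
}

seg_prob_enumerate <- function(ped, q, cons) {
  n <- nrow(ped)
  states <- as.matrix(expand.grid(rep(list(0:2), n)))  # columns follow ped order
  w <- rep(1, nrow(states))
  prior <- hwe_prior(q)
  T <- transmission_array()
  idx <- stats::setNames(seq_len(n), ped$member_id)
  for (i in seq_len(n)) {
    gi <- states[, i] + 1L
    if (is.na(ped$father_id[i])) {
      w <- w * prior[gi]
    } else {
      gf <- states[, idx[[ped$father_id[i]]]] + 1L
      gm <- states[, idx[[ped$mother_id[i]]]] + 1L
      w <- w * T[cbind(gi, gf, gm)]
    }
    w <- w * cons[[ped$member_id[i]]][gi]
  }
  sum(w)
}

# --- sum-product variable elimination over the pedigree DAG ----------------

factor_product_marginalize <- function(factors, elim_var) {
  vars <- sort(unique(unlist(lapply(factors, `[[`, "vars"))))
  u <- length(vars)
  grid <- as.matrix(expand.grid(rep(list(1:3), u)))
  vals <- rep(1, nrow(grid))
  for (f in factors) {
    cols <- match(f$vars, vars)
    vals <- vals * f$tab[grid[, cols, drop = FALSE]]
  }
  keep <- setdiff(vars, elim_var)
  if (length(keep) == 0) {
    return(list(vars = integer(0), tab = array(sum(vals), dim = 1)))
  }
  kcols <- match(keep, vars)
  key <- grid[, kcols, drop = FALSE]
  # linear index over kept variables
  lin <- as.vector((key - 1) %*% (3^(seq_along(keep) - 1))) + 1
  tab <- array(0, dim = rep(3, length(keep)))
  agg <- rowsum(vals, lin)
  tab[as.integer(rownames(agg))] <- agg
  list(vars = keep, tab = tab)
}

seg_prob_peeling <- function(ped, q, cons) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$member_id)
  prior <- hwe_prior(q)
  T <- transmission_array()
  factors <- list()
  add <- function(vars, tab) factors[[length(factors) + 1]] <<- list(vars = vars, tab = tab)
  for (i in seq_len(n)) {
    ci <- cons[[ped$member_id[i]]]
    if (is.na(ped$father_id[i])) {
      add(i, prior * ci)
    } else {
      fi <- idx[[ped$father_id[i]]]
      mi <- idx[[ped$mother_id[i]]]
      tab <- T  # dims: child, father, mother
      tab <- sweep(tab, 1, ci, `*`)
      # store with vars sorted ascending to match grid indexing
      vars <- c(i, fi, mi)
      ord <- order(vars)
      add(vars[ord], aperm(tab, ord))
    }
  }
  # eliminate children before parents: reverse pedigree order is reverse
  # topological (ped is founders-first)
  log_scale <- 0
  for (v in rev(seq_len(n))) {
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    merged <- factor_product_marginalize(factors[touch], v)
    mx <- max(merged$tab)
    if (mx > 0) {
      merged$tab <- merged$tab / mx
      log_scale <- log_scale + log(mx)
    }
    factors <- c(factors[!touch], list(merged))
  }
  const <- prod(vapply(factors, function(f) as.numeric(f$tab[1]), numeric(1)))
  exp(log_scale) * const
}

#' Joint segregation probability across families
#'
#' Under the null the families are independent, so the joint probability of
#' simultaneous segregation is the product of the per-family probabilities.
#'
#' @param p_values Numeric vector (or named vector) of per-family
#'   segregation probabilities in `[0, 1]`.
#' @return The product.
#' @export
joint_segregation_prob <- function(p_values) {
  p_values <- unlist(p_values)
  if (length(p_values) == 0) stop("no per-family probabilities supplied")
  if (any(p_values < 0 | p_values > 1)) stop("probabilities must be in [0, 1]")
  prod(p_values)
}

#' Gene-dropping estimate of the joint segregation probability
#'
#' Per replicate, founder genotypes are drawn at Hardy-Weinberg proportions
#' with frequency `q` and alleles are dropped through each pedigree; the
#' replicate is an event when the segregation pattern (all affected carry,
#' no unaffected carries) holds simultaneously in every family. Returns the
#' estimator `(1 + events) / (n_sims + 1)`, which never reports exactly zero.
#'
#' @param families List of family data.frames.
#' @param q Founder alternate-allele frequency.
#' @param n_sims Number of replicates.
#' @param seed Optional integer seed.
#' @param chunk Replicates per vectorised block (memory bound).
#' @return The simulated joint probability.
#' @export
gene_drop_p <- function(families, q, n_sims, seed = NULL, chunk = 1e6) {
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  peds <- lapply(families, build_pedigree)
  events <- 0
  left <- n_sims
  while (left > 0) {
    m <- min(left, chunk)
    ok <- rep(TRUE, m)
    for (ped in peds) {
      ok <- ok & gene_drop_family_events(ped, q, m)
    }
    events <- events + sum(ok)
    left <- left - m
  }
  (1 + events) / (n_sims + 1)
}

gene_drop_family_events <- function(ped, q, m) {
  n <- nrow(ped)
  dos <- matrix(0L, nrow = m, ncol = n)
  idx <- stats::setNames(seq_len(n), ped$member_id)
  for (i in seq_len(n)) {
    if (is.na(ped$father_id[i])) {
      dos[, i] <- stats::rbinom(m, 2L, q)
    } else {
      gf <- dos[, idx[[ped$father_id[i]]]]
      gm <- dos[, idx[[ped$mother_id[i]]]]
      dos[, i] <- stats::rbinom(m, 1L, gf / 2) + stats::rbinom(m, 1L, gm / 2)
    }
  }
  ok <- rep(TRUE, m)
  for (i in seq_len(n)) {
    if (ped$phenotype[i] == "affected") ok <- ok & dos[, i] >= 1L
    else if (ped$phenotype[i] == "unaffected") ok <- ok & dos[, i] == 0L
  }
  ok
}

#' Run the segregation test over a set of families
#'
#' @param cohort A cohort object.
#' @param q Founder alternate-allele frequency.
#' @param families Character vector of family ids (default all).
#' @param n_sims Gene-dropping replicates for the simulated joint
#'   probability; 0 skips simulation.
#' @param seed Optional integer seed for the simulation.
#' @param ... Passed to [family_segregation_prob()].
#' @return List with `per_family` (named probabilities), `joint`, `sim_p`
#'   and `n_sims`.
#' @export
run_segregation <- function(cohort, q, families = family_ids(cohort),
                            n_sims = 0, seed = NULL, ...) {
  fams <- lapply(families, function(fid) family_members(cohort, fid))
  p <- vapply(fams, family_segregation_prob, numeric(1), q = q, ...)
  names(p) <- families
  joint <- joint_segregation_prob(p)
  sim <- if (n_sims > 0) gene_drop_p(fams, q, n_sims, seed = seed) else NULL
  list(per_family = p, joint = joint, sim_p = sim,
       n_sims = if (n_sims > 0) n_sims else NULL, q = q)
}
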