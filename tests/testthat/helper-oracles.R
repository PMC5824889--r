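# Independent oracles and shared fixtures, built in code.

# ---- exhaustive isotope-pattern oracle (multinomial enumeration) ----------

compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  do.call(rbind, lapply(0:n, function(i) cbind(i, compositions(n - i, k - 1L))))
}

iso_pattern_oracle <- function(counts, n_peaks = 10L) {
  iso <- isotope_table()
  acc <- data.frame(shift = 0L, off = 0, p = 1)
  for (el in names(counts)) {
    rows <- iso[iso$element == el, , drop = FALSE]
    rows <- rows[order(rows$mass), ]
    ab <- rows$abundance / sum(rows$abundance)
    k_shift <- as.integer(round(rows$mass - rows$mass[1]))
    d_off <- rows$mass - rows$mass[1]
    comp <- compositions(counts[[el]], nrow(rows))
    el_tab <- data.frame(
      shift = as.integer(comp %*% k_shift),
      off = as.numeric(comp %*% d_off),
      p = apply(comp, 1, function(m) stats::dmultinom(m, prob = ab)))
    # cross join with the accumulator
    idx <- expand.grid(a = seq_len(nrow(acc)), b = seq_len(nrow(el_tab)))
    acc <- data.frame(shift = acc$shift[idx$a] + el_tab$shift[idx$b],
                      off = acc$off[idx$a] + el_tab$off[idx$b],
                      p = acc$p[idx$a] * el_tab$p[idx$b])
  }
  p <- tapply(acc$p, acc$shift, sum)
  off <- tapply(acc$p * acc$off, acc$shift, sum) / p
  ord <- order(as.integer(names(p)))
  p <- as.numeric(p[ord]); off <- as.numeric(off[ord])
  rel <- p / max(p)
  keep <- rel >= 1e-4; keep[1] <- TRUE
  idx <- which(keep)[seq_len(min(n_peaks, sum(keep)))]
  data.frame(offset = off[idx], abundance = rel[idx] / max(rel[idx]))
}

# ---- naive greedy bucketing oracle ----------------------------------------

greedy_oracle_partition <- function(features, rt_width = 0.2,
                                    mz_width = 0.03, max_pass = 10L) {
  hw_mz <- mz_width / 2; hw_rt <- rt_width / 2
  ord <- order(-features$intensity, features$mz, features$rt,
               features$dataset_id, features$feature_id)
  f <- features[ord, ]
  assign_block <- function(mz, rt) {
    buckets <- list()
    assignment <- integer(length(mz))
    for (i in seq_along(mz)) {
      best <- 0L; best_d <- Inf
      for (b in seq_along(buckets)) {
        cm <- mean(mz[buckets[[b]]]); cr <- mean(rt[buckets[[b]]])
        if (abs(cm - mz[i]) <= hw_mz && abs(cr - rt[i]) <= hw_rt) {
          d <- sqrt(((cm - mz[i]) / hw_mz)^2 + ((cr - rt[i]) / hw_rt)^2)
          if (d < best_d) { best_d <- d; best <- b }
        }
      }
      if (best == 0L) {
        buckets[[length(buckets) + 1L]] <- i
        assignment[i] <- length(buckets)
      } else {
        buckets[[best]] <- c(buckets[[best]], i)
        assignment[i] <- best
      }
    }
    assignment
  }
  assignment <- assign_block(f$mz, f$rt)
  for (pass in seq_len(max_pass)) {
    cm <- tapply(f$mz, assignment, mean)[as.character(assignment)]
    cr <- tapply(f$rt, assignment, mean)[as.character(assignment)]
    viol <- abs(f$mz - cm) > hw_mz | abs(f$rt - cr) > hw_rt
    if (!any(viol)) break
    if (pass == max_pass) {
      assignment[viol] <- max(assignment) + seq_len(sum(viol))
      break
    }
    assignment[viol] <- max(assignment) + assign_block(f$mz[viol], f$rt[viol])
    assignment <- match(assignment, sort(unique(assignment)))
  }
  # canonical partition: sorted member-key sets
  keys <- paste(f$dataset_id, f$feature_id)
  parts <- lapply(split(keys, assignment), sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

partition_of <- function(assignment) {
  keys <- paste(assignment$dataset_id, assignment$feature_id)
  parts <- lapply(split(keys, assignment$bucket_id), sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

# ---- brute-force cosine distance ------------------------------------------

cosine_oracle <- function(a, b) {
  a <- as.numeric(a) > 0; b <- as.numeric(b) > 0
  if (sum(a) == 0 && sum(b) == 0) return(0)
  if (sum(a) == 0 || sum(b) == 0) return(1)
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] && b[i])
  1 - s / sqrt(sum(a) * sum(b))
}

# ---- naive all-pairs de-replication matcher -------------------------------

match_oracle <- function(features, library, tol) {
  out <- list()
  for (j in seq_len(nrow(features))) {
    ab <- unlist(features[j, intersect(c("iso1", "iso2", "iso3"),
                                       names(features))])
    ab <- ab[!is.na(ab)]
    for (i in seq_len(nrow(library))) {
      theo <- theoretical_isotope_pattern(library$counts[[i]], 3L)$abundance
      for (a in library$adducts[[i]]) {
        mzt <- adduct_mz(library$neutral_mass[i], a)
        ppm <- (features$mz[j] - mzt) / mzt * 1e6
        if (abs(ppm) >= tol$ppm_max) next
        if (abs(features$rt[j] - library$reference_rt[i]) > tol$rt_dev_max)
          next
        if (length(ab) > 0 &&
            isotope_fit_score(ab, theo) >= tol$iso_score_max) next
        out[[length(out) + 1L]] <- data.frame(
          feature_id = features$feature_id[j],
          compound_name = library$compound_name[i], adduct = a)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(feature_id = character(),
                      compound_name = character(), adduct = character()))
  }
  do.call(rbind, out)
}

# ---- shared fixtures (simulated once per test run) ------------------------

.fixtures <- new.env()

default_cohort <- function(seed = 42L) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_cohort(cohort_spec(seed = seed))
  }
  .fixtures[[key]]
}

# preprocessed + bucketed products of the default cohort
default_products <- function(seed = 42L) {
  key <- paste0("products_", seed)
  if (is.null(.fixtures[[key]])) {
    co <- default_cohort(seed)
    pre <- preprocess_cohort(co$features, co$blanks)
    bk <- bucket_features(pre$features)
    occ <- build_occurrence_matrix(bk$assignment,
                                   unique(co$features$dataset_id))
    .fixtures[[key]] <- list(cohort = co, pre = pre, bk = bk, occ = occ,
                             registry = dataset_registry(co$features))
  }
  .fixtures[[key]]
}

# rowithocin-like reference record used across dereplication tests
rowithocin_library <- function() {
  validate_compound_library(tibble::tibble(
    compound_name = "rowithocin A", family_name = "rowithocins",
    formula = "C35H47O7P", reference_rt = 16.8,
    adducts = list(c("[M+H]+", "[M-H]-"))))
}
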