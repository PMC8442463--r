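#' Simulate a ground-truth-labeled differentiation time-course bundle
#'
#' Generates a complete synthetic input set for the pipeline: per-stage
#' H3K27ac peak sets whose SE-level trajectories follow the three temporal
#' archetypes, a count table and library sizes, expression profiles coupled
#' to their true-target SE signals plus decoy genes, TSS annotation, and
#' (optionally) toy Hi-C contact matrices with planted TADs, planted
#' frequently-interacting bins, and a two-sign compartment track. Every
#' planted quantity is returned in `$truth`.
#'
#' Archetypes (one SE locus per row, `constituents_range` elements each):
#' \describe{
#'   \item{Con}{all elements active at a constant base level across all
#'     stages (multiplicative log-normal noise only).}
#'   \item{TH}{at least one element active from stage 0; remaining
#'     elements switch on at staggered stages drawn uniformly from
#'     `onset_stage_range`.}
#'   \item{DN}{all elements near baseline until `dn_onset_stage`, then
#'     simultaneously high.}
#' }
#' Inactive elements sit at `inactive_rpm`; active at `active_rpm`; all
#' signals are multiplied by log-normal noise with coefficient of
#' variation `noise_cv`. True-target gene expression follows the SE's
#' realized quantile-normalized per-stage signal perturbed by Gaussian
#' noise with sd equal to `coupling_noise` times the signal's temporal sd
#' (population correlation about `1/sqrt(1 + coupling_noise^2)`), then
#' scaled to a 10 RPKM maximum. Each SE also gets decoy genes inside the
#' 100 kb window: one flat-noise profile and one declining profile.
#'
#' @param n_stages Number of stages T (default 5).
#' @param n_se_per_class SEs per archetype (default 100).
#' @param constituents_range Min/max constituents per SE (default `c(3, 15)`).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal signal noise (default 0.1).
#' @param onset_stage_range 0-based stage range for staggered TH element
#'   onsets (default `c(1, n_stages - 1)`).
#' @param dn_onset_stage 0-based onset stage of DN elements (default
#'   `n_stages - 2`).
#' @param active_rpm,inactive_rpm,background_rpm RPM levels of active SE
#'   elements, inactive elements, and background regular enhancers
#'   (defaults 20, 0.5, 3).
#' @param n_background_per_se Regular-enhancer peaks interleaved per SE
#'   slot (default 2).
#' @param library_size Mapped reads per stage (default 2e7).
#' @param coupling_noise Target-gene coupling noise as a fraction of the
#'   SE signal's temporal sd (default 0.2).
#' @param hic Also generate the toy Hi-C section (default `TRUE`).
#' @param tad_bins,fire_bins,comp_bins Bin counts of the TAD (40 kb), FIRE
#'   (50 kb) and compartment (50 kb) toy chromosomes.
#' @param fire_frac_true Fraction of FIRE-chromosome bins with planted
#'   inflated local contacts (default 0.08).
#' @param fire_inflation Local-contact inflation factor of planted FIRE
#'   bins (default 10).
#' @param master_seed Integer seed; the whole bundle is a deterministic
#'   function of it.
#' @return A list of class `"se_bundle"` with elements `stages`, `peaks`,
#'   `counts` (coordinate-keyed long table), `library_sizes`,
#'   `expression`, `tss`, `chrom_sizes`, `hic` (or `NULL`), `truth`, and
#'   `config`.
#' @export
simulate_se_bundle <- function(n_stages = 5, n_se_per_class = 100,
                               constituents_range = c(3, 15),
                               noise_cv = 0.1,
                               onset_stage_range = c(1, n_stages - 1),
                               dn_onset_stage = n_stages - 2,
                               active_rpm = 20, inactive_rpm = 0.5,
                               background_rpm = 3,
                               n_background_per_se = 2,
                               library_size = 2e7,
                               coupling_noise = 0.2,
                               hic = TRUE,
                               tad_bins = 250, fire_bins = 400,
                               comp_bins = 200,
                               fire_frac_true = 0.08, fire_inflation = 10,
                               master_seed = 1) {
  stopifnot(n_stages >= 3, n_se_per_class > 0, noise_cv >= 0)
  stages <- paste0("t", seq_len(n_stages) - 1)
  classes <- rep(c("Con", "TH", "DN"), each = n_se_per_class)
  n_se <- length(classes)

  pitch <- 250000L
  peak_w <- 1500L
  peak_gap <- 3000L
  chrom <- "chrS"
  chrom_len <- pitch * (n_se + 1L)
  # the SE span must end before the background peaks at slot + 150 kb
  if (constituents_range[2] * (peak_w + peak_gap) > 140000) {
    abort("infeasible geometry: SE slots exceed the slot pitch")
  }

  noise <- function(n) {
    if (noise_cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  with_seed(master_seed, {
    # ---- SE loci, elements, and onset stages -----------------------------
    n_cons <- sample(constituents_range[1]:constituents_range[2], n_se,
                     replace = TRUE)
    elements <- map(seq_len(n_se), function(i) {
      slot0 <- 100000L + (i - 1L) * pitch
      k <- n_cons[i]
      st <- slot0 + (seq_len(k) - 1L) * (peak_w + peak_gap)
      onset <- switch(classes[i],
        Con = rep(0L, k),
        DN = rep(as.integer(dn_onset_stage), k),
        TH = {
          o <- sample(onset_stage_range[1]:onset_stage_range[2], k,
                      replace = TRUE)
          o[sample.int(k, 1)] <- 0L # at least one early element
          as.integer(o)
        })
      tibble(true_se = sprintf("true_se%03d", i), se_class = classes[i],
             chrom = chrom, start = st, end = st + peak_w,
             element = sprintf("true_se%03d_e%02d", i, seq_len(k)),
             onset = onset)
    })
    elements <- bind_rows(elements)

    bg_start <- map(seq_len(n_se), function(i) {
      slot0 <- 100000L + (i - 1L) * pitch
      slot0 + 150000L + (seq_len(n_background_per_se) - 1L) * 30000L
    })
    bg <- tibble(chrom = chrom, start = unlist(bg_start))
    bg$end <- bg$start + peak_w
    bg$element <- sprintf("bg%04d", seq_len(nrow(bg)))

    # ---- per-element per-stage RPM signal --------------------------------
    stage_idx <- seq_len(n_stages) - 1L
    el_sig <- matrix(0, nrow(elements), n_stages,
                     dimnames = list(elements$element, stages))
    for (s in seq_len(n_stages)) {
      active <- elements$onset <= stage_idx[s]
      base <- ifelse(active, active_rpm, inactive_rpm)
      el_sig[, s] <- base * noise(nrow(elements))
    }
    bg_sig <- matrix(background_rpm * noise(nrow(bg) * n_stages),
                     nrow(bg), n_stages,
                     dimnames = list(bg$element, stages))

    # ---- per-stage peak sets (element present iff active; bg always) ----
    pk_rows <- map(seq_len(n_stages), function(s) {
      pres <- elements[elements$onset <= stage_idx[s], , drop = FALSE]
      bind_rows(
        tibble(chrom = pres$chrom, start = pres$start, end = pres$end,
               peak_id = paste0(pres$element, "_", stages[s]),
               stage = stages[s]),
        tibble(chrom = bg$chrom, start = bg$start, end = bg$end,
               peak_id = paste0(bg$element, "_", stages[s]),
               stage = stages[s])
      )
    })
    peaks <- bind_rows(pk_rows) |> arrange(.data$stage, .data$start)

    # ---- coordinate-keyed count table (all elements, all stages) ---------
    all_sig <- rbind(el_sig, bg_sig)
    coords <- bind_rows(
      elements[, c("chrom", "start", "end", "element")],
      bg[, c("chrom", "start", "end", "element")]
    )
    counts <- tidyr::expand_grid(element = coords$element, stage = stages) |>
      left_join(coords, by = "element") |>
      mutate(count = round(all_sig[cbind(.data$element, .data$stage)] *
                             library_size / 1e6)) |>
      select("chrom", "start", "end", "stage", "count")
    library_sizes <- tibble(stage = stages, total_reads = library_size)

    # ---- expression: true targets coupled to measured SE signal ----------
    sig_tbl <- new_signal_matrix(
      dplyr::bind_cols(tibble(peak_id = rownames(all_sig)),
                       as_tibble(as.data.frame(all_sig))),
      stages, normalized = FALSE)
    qn <- signal_values(quantile_normalize(sig_tbl))
    se_signal <- t(sapply(split(elements$element, elements$true_se),
                          function(ids) colSums(qn[ids, , drop = FALSE])))
    se_meta <- elements |>
      group_by(.data$true_se, .data$se_class) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop") |>
      arrange(.data$true_se)

    target_rows <- map(seq_len(nrow(se_meta)), function(i) {
      s <- se_signal[se_meta$true_se[i], ]
      y <- s + stats::rnorm(n_stages, 0, coupling_noise * sd(s))
      y <- pmax(y, 0)
      if (max(y) > 0) y <- 10 * y / max(y)
      gt <- sprintf("gene_target%03d", i)
      d1 <- sprintf("gene_decoyA%03d", i)
      d2 <- sprintf("gene_decoyB%03d", i)
      # decoys: expression independent of any SE signal (iid noise around
      # a flat base level)
      dec1 <- 5 * noise(n_stages)
      dec2 <- 8 * noise(n_stages)
      list(
        expr = tibble(gene_id = c(gt, d1, d2)) |>
          dplyr::bind_cols(as_tibble(as.data.frame(
            rbind(y, dec1, dec2), row.names = FALSE)) |>
              setNames(stages)),
        tss = tibble(gene_id = c(gt, d1, d2), chrom = chrom,
                     tss = c(se_meta$end[i] + 20000L,
                             se_meta$start[i] - 30000L,
                             se_meta$start[i] - 50000L),
                     strand = "+"),
        truth = tibble(gene_id = c(gt, d1, d2),
                       role = c("target", "decoy", "decoy"),
                       true_se = se_meta$true_se[i])
      )
    })
    expression <- bind_rows(map(target_rows, "expr"))
    tss <- bind_rows(map(target_rows, "tss"))
    gene_truth <- bind_rows(map(target_rows, "truth"))

    # ---- toy Hi-C --------------------------------------------------------
    hic_part <- NULL
    if (hic) {
      hic_part <- simulate_hic(stages, tad_bins = tad_bins,
                               fire_bins = fire_bins, comp_bins = comp_bins,
                               fire_frac_true = fire_frac_true,
                               fire_inflation = fire_inflation)
    }

    truth <- list(
      se = se_meta |>
        rename(class = "se_class") |>
        mutate(chrom = chrom, n_constituents = n_cons),
      elements = elements,
      genes = gene_truth,
      tad_boundaries = if (hic) hic_part$truth$tad_boundaries else NULL,
      fires = if (hic) hic_part$truth$fires else NULL,
      compartments = if (hic) hic_part$truth$compartments else NULL
    )
    if (hic) hic_part$truth <- NULL

    structure(
      list(stages = stages, peaks = peaks, counts = counts,
           library_sizes = library_sizes, expression = expression,
           tss = tss,
           chrom_sizes = stats::setNames(chrom_len, chrom),
           hic = hic_part, truth = truth,
           config = list(n_stages = n_stages,
                         n_se_per_class = n_se_per_class,
                         constituents_range = constituents_range,
                         noise_cv = noise_cv,
                         onset_stage_range = onset_stage_range,
                         dn_onset_stage = dn_onset_stage,
                         active_rpm = active_rpm,
                         inactive_rpm = inactive_rpm,
                         background_rpm = background_rpm,
                         library_size = library_size,
                         coupling_noise = coupling_noise,
                         master_seed = master_seed)),
      class = "se_bundle")
  })
}

# Toy Hi-C generator: planted block TADs at 40 kb, planted high-local-contact
# bins at 50 kb, and a blocky two-sign compartment track. Runs inside the
# caller's seeded RNG session.
simulate_hic <- function(stages, tad_bins, fire_bins, comp_bins,
                         fire_frac_true, fire_inflation) {
  n_stages <- length(stages)
  # ---- TAD chromosome (40 kb): contiguous blocks of 30..60 bins ----------
  tad_res <- 40000L
  sizes <- integer(0)
  while (sum(sizes) < tad_bins) {
    sizes <- c(sizes, sample(30:60, 1))
  }
  sizes[length(sizes)] <- tad_bins - sum(head(sizes, -1))
  if (tail(sizes, 1) < 30) { # merge a short trailing block
    sizes[length(sizes) - 1] <- sizes[length(sizes) - 1] + tail(sizes, 1)
    sizes <- head(sizes, -1)
  }
  block <- rep(seq_along(sizes), sizes)
  boundaries <- which(diff(block) != 0) # boundary between bin b and b+1
  d <- abs(outer(seq_len(tad_bins), seq_len(tad_bins), `-`))
  same <- outer(block, block, `==`)
  base <- ifelse(same, 50 * exp(-d / 25), 0.1)
  diag(base) <- 100
  tad <- map(stages, function(s) {
    m <- base * matrix(stats::rlnorm(tad_bins^2, -0.005, 0.1),
                       tad_bins, tad_bins)
    m <- (m + t(m)) / 2
    structure(list(chrom = "chrT", resolution = tad_res,
                   n_bins = tad_bins, mat = m), class = "contact_matrix")
  })
  names(tad) <- stages

  # ---- FIRE chromosome (50 kb): power-law decay + inflated local bins ----
  fire_res <- 50000L
  df <- abs(outer(seq_len(fire_bins), seq_len(fire_bins), `-`))
  decay <- ifelse(df == 0, 120, 60 / pmax(df, 1))
  n_true <- max(1L, round(fire_frac_true * fire_bins))
  fire_true <- sort(sample(5:(fire_bins - 5), n_true))
  boost <- matrix(1, fire_bins, fire_bins)
  for (b in fire_true) {
    lo <- max(1, b - 4):min(fire_bins, b + 4)
    boost[b, lo] <- fire_inflation
    boost[lo, b] <- fire_inflation
  }
  fire <- map(stages, function(s) {
    lam <- decay * boost
    m <- matrix(stats::rpois(fire_bins^2, lam), fire_bins, fire_bins)
    m <- pmax(m, t(m))
    structure(list(chrom = "chrF", resolution = fire_res,
                   n_bins = fire_bins, mat = m), class = "contact_matrix")
  })
  names(fire) <- stages

  # ---- compartment chromosome (50 kb): four planted category blocks ------
  comp_res <- 50000L
  cat_block <- rep(c("stableA", "stableB", "AtoB", "BtoA"),
                   length.out = 4)[rep(1:4, each = ceiling(comp_bins / 4))]
  cat_block <- cat_block[seq_len(comp_bins)]
  mag1 <- stats::runif(comp_bins, 0.2, 1)
  mag2 <- stats::runif(comp_bins, 0.2, 1)
  s1 <- ifelse(cat_block %in% c("stableA", "AtoB"), mag1, -mag1)
  s2 <- ifelse(cat_block %in% c("stableA", "BtoA"), mag2, -mag2)
  bins <- tibble(chrom = "chrC",
                 start = (seq_len(comp_bins) - 1L) * comp_res,
                 end = seq_len(comp_bins) * comp_res)
  pc1_first <- mutate(bins, pc1 = s1)
  pc1_last <- mutate(bins, pc1 = s2)

  list(
    tad = tad, fire = fire,
    pc1_first = pc1_first, pc1_last = pc1_last,
    tad_resolution = tad_res, fire_resolution = fire_res,
    truth = list(
      tad_boundaries = tibble(chrom = "chrT", bin = boundaries - 1L,
                              start = (boundaries - 1L) * tad_res,
                              end = boundaries * tad_res),
      fires = tibble(chrom = "chrF", bin = fire_true - 1L,
                     start = (fire_true - 1L) * fire_res,
                     end = fire_true * fire_res),
      compartments = mutate(bins, category = cat_block)
    )
  )
}

#' @export
print.se_bundle <- function(x, ...) {
  cat(sprintf(
    "<se_bundle> %d stages, %d planted SEs (%s), %d genes, seed %d\n",
    length(x$stages), nrow(x$truth$se),
    paste(names(table(x$truth$se$class)), table(x$truth$se$class),
          sep = "=", collapse = " "),
    nrow(x$expression), x$config$master_seed))
  invisible(x)
}

#' Reverse the stage axis of a synthetic bundle
#'
#' Produces the decommission counterpart of an activation bundle: every
#' stage-indexed component (peak sets, counts, expression columns, Hi-C
#' matrices) is re-indexed so the last stage becomes the first. A DN
#' activation archetype (simultaneous late gain) becomes a DN decommission
#' archetype (rapid early loss). Reversing twice is the identity.
#'
#' @param bundle An `se_bundle`.
#' @return The reversed `se_bundle` (stage labels keep their original
#'   names but now denote the reversed order).
#' @export
time_reverse <- function(bundle) {
  stages <- bundle$stages
  revmap <- setNames(stages, rev(stages)) # new label -> old label
  out <- bundle
  # peaks/counts: stage s now carries what old stage rev(s) had
  out$peaks <- bundle$peaks |>
    mutate(stage = names(revmap)[match(.data$stage, revmap)],
           peak_id = sub(paste0("_(", paste(stages, collapse = "|"), ")$"),
                         "", .data$peak_id)) |>
    mutate(peak_id = paste0(.data$peak_id, "_", .data$stage)) |>
    arrange(.data$stage, .data$start)
  out$counts <- bundle$counts |>
    mutate(stage = names(revmap)[match(.data$stage, revmap)])
  out$expression <- bundle$expression[, c("gene_id", rev(stages))]
  names(out$expression) <- c("gene_id", stages)
  if (!is.null(bundle$hic)) {
    out$hic$tad <- setNames(rev(bundle$hic$tad), stages)
    out$hic$fire <- setNames(rev(bundle$hic$fire), stages)
    out$hic$pc1_first <- bundle$hic$pc1_last
    out$hic$pc1_last <- bundle$hic$pc1_first
  }
  out$truth$elements <- bundle$truth$elements |>
    mutate(onset = length(stages) - 1L - .data$onset) # last active stage
  out$config$time_reversed <- !isTRUE(bundle$config$time_reversed)
  out
}

#' Write a synthetic bundle to disk in the pipeline's file formats
#'
#' Emits per-stage peak BEDs, a coordinate-keyed count TSV, library-size
#' TSV, expression TSV, TSS TSV, per-stage contact-matrix triplet TSVs,
#' PC1 bedGraphs, and a JSON manifest recording the seed and file paths.
#'
#' @param bundle An `se_bundle`.
#' @param dir Output directory (created if needed).
#' @return The manifest as a list, invisibly; files under `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (s in bundle$stages) {
    p <- file.path(dir, paste0("peaks_", s, ".bed"))
    write_bed(bundle$peaks[bundle$peaks$stage == s,
                           c("chrom", "start", "end", "peak_id")], p)
    paths[[paste0("peaks_", s)]] <- p
  }
  readr::write_tsv(bundle$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(bundle$library_sizes, file.path(dir, "library_sizes.tsv"))
  readr::write_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(bundle$tss, file.path(dir, "tss.tsv"))
  paths$counts <- file.path(dir, "counts.tsv")
  if (!is.null(bundle$hic)) {
    for (s in bundle$stages) {
      for (kind in c("tad", "fire")) {
        cm <- bundle$hic[[kind]][[s]]
        idx <- which(upper.tri(cm$mat, diag = TRUE) & cm$mat > 0,
                     arr.ind = TRUE)
        trip <- tibble(chrom = cm$chrom, bin_i = idx[, 1] - 1L,
                       bin_j = idx[, 2] - 1L,
                       count = cm$mat[idx])
        p <- file.path(dir, sprintf("hic_%s_%s.tsv", kind, s))
        readr::write_tsv(trip, p)
        paths[[sprintf("hic_%s_%s", kind, s)]] <- p
      }
    }
    write_bed(bundle$hic$pc1_first, file.path(dir, "pc1_first.bedGraph"))
    write_bed(bundle$hic$pc1_last, file.path(dir, "pc1_last.bedGraph"))
  }
  manifest <- list(master_seed = bundle$config$master_seed,
                   stages = bundle$stages, files = paths)
  jsonlite::write_json(manifest, file.path(dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
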