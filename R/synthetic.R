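#' Simulation configuration
#'
#' Parameters of the synthetic promoter study: dataset shape (genes,
#' window, orthology), motif models, the planting table (ground-truth TFBS
#' copies per gene per TF), ortholog divergence, and the noise channel of
#' the simulated tool ensemble.
#'
#' @param n_genes number of human genes.
#' @param promoter_up,promoter_down bp upstream / downstream of the TSS
#'   (defaults 5000 / 500).
#' @param gc_content background GC fraction in `[0, 1]`.
#' @param n_tfs number of TF motif models.
#' @param pwm_length motif length in bp.
#' @param pwm_info_bits per-column motif information content, bits.
#' @param planting_table named list: gene id -> named integer vector of
#'   TF id -> copy count. `NULL` means no planted sites.
#' @param ortholog_fraction fraction of human genes with a mouse ortholog.
#' @param substitution_rate per-bp substitution probability for the mouse
#'   promoter background (planted sites are conserved exactly).
#' @param tool_sensitivities per-main-tool detection probability of a true
#'   site; length `n_main_tools`.
#' @param tool_fp_rate expected false main-tool hits per kb of promoter.
#' @param supportive_fp_prob probability a supportive tool falsely reports
#'   an unplanted TF.
#' @param n_main_tools,n_supportive_tools ensemble sizes (defaults 5 / 4).
#' @param seed master integer seed; all generator output is a pure function
#'   of the configuration including this seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 49,
                              promoter_up = 5000, promoter_down = 500,
                              gc_content = 0.45,
                              n_tfs = 30, pwm_length = 10, pwm_info_bits = 1.3,
                              planting_table = NULL,
                              ortholog_fraction = 43 / 49,
                              substitution_rate = 0.15,
                              tool_sensitivities = rep(0.9, 5),
                              tool_fp_rate = 0.2,
                              supportive_fp_prob = 0.05,
                              n_main_tools = 5, n_supportive_tools = 4,
                              seed = 1) {
  probs <- c(gc_content, ortholog_fraction, substitution_rate,
             tool_sensitivities, supportive_fp_prob)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities and fractions must lie in [0, 1]")
  }
  if (length(tool_sensitivities) != n_main_tools) {
    stop("tool_sensitivities must have length n_main_tools")
  }
  if (n_main_tools < 1 && n_supportive_tools < 1) {
    stop("at least one tool must be configured")
  }
  if (promoter_up + promoter_down <= pwm_length) {
    stop("promoter window must be longer than the motif")
  }
  if (tool_fp_rate < 0) stop("tool_fp_rate must be >= 0")
  if (!is.null(planting_table)) {
    copies <- unlist(planting_table)
    if (length(copies) && (any(copies < 0) || any(copies != round(copies)))) {
      stop("planting copy counts must be non-negative integers")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), promoter_up = as.integer(promoter_up),
         promoter_down = as.integer(promoter_down), gc_content = gc_content,
         n_tfs = as.integer(n_tfs), pwm_length = as.integer(pwm_length),
         pwm_info_bits = pwm_info_bits, planting_table = planting_table,
         ortholog_fraction = ortholog_fraction,
         substitution_rate = substitution_rate,
         tool_sensitivities = tool_sensitivities,
         tool_fp_rate = tool_fp_rate, supportive_fp_prob = supportive_fp_prob,
         n_main_tools = as.integer(n_main_tools),
         n_supportive_tools = as.integer(n_supportive_tools),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<simulation_config> %d genes (-%d/+%d bp), %d TFs (L=%d, %.2f bits/col),\n",
    "  ortholog fraction %.2f, substitution %.3f/bp, %d main + %d supportive tools, seed %d\n"),
    x$n_genes, x$promoter_up, x$promoter_down, x$n_tfs, x$pwm_length,
    x$pwm_info_bits, x$ortholog_fraction, x$substitution_rate,
    x$n_main_tools, x$n_supportive_tools, x$seed))
  invisible(x)
}

## gene / TF id helpers shared by the generators
sim_gene_ids <- function(n) sprintf("G%02d", seq_len(n))
mouse_id <- function(gene_id) paste0(gene_id, "m")

empty_truth <- function() {
  data.frame(gene_id = character(), tf_id = character(), start = integer(),
             strand = character(), copy = integer(), stringsAsFactors = FALSE)
}

## sample one site sequence from a PWM (per-column base draw)
sample_site <- function(x) {
  paste(apply(x$probabilities, 2, function(p) sample(DNA_BASES, 1, prob = p)),
        collapse = "")
}

#' Generate a synthetic promoter set with planted binding sites
#'
#' Human promoters are i.i.d. background at the configured GC content, with
#' TFBS copies planted per the planting table at random non-overlapping
#' positions and random strands (site sequences are drawn from the TF's
#' PWM). The first `round(ortholog_fraction * n_genes)` genes get mouse
#' orthologs: the human background diverged by i.i.d. substitution at
#' `substitution_rate`, with the planted sites re-inserted unchanged
#' (motif conservation). Mouse gene ids are the human id plus `"m"`.
#' Module labels cycle through the core plus ten pathway modules.
#'
#' @param config a `simulation_config`.
#' @param pwms optional motif models; by default generated from the config
#'   (`n_tfs`, `pwm_length`, `pwm_info_bits`) under a derived child seed.
#' @return list with `promoters` (list of `promoter_record`, human then
#'   mouse), `truth` (data.frame gene_id, tf_id, start, strand, copy; start
#'   is TSS-relative), and `pwms`.
#' @export
generate_promoter_set <- function(config, pwms = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- derive_seeds(config$seed, 3)
  if (is.null(pwms)) {
    pwms <- generate_pwms(config$n_tfs, config$pwm_length,
                          config$pwm_info_bits, seeds[1])
  }
  tf_ids <- vapply(pwms, `[[`, "", "tf_id")
  genes <- sim_gene_ids(config$n_genes)
  plant <- config$planting_table
  if (!is.null(plant)) {
    if (length(setdiff(names(plant), genes))) {
      stop("planting_table references unknown genes: ",
           paste(setdiff(names(plant), genes), collapse = ", "))
    }
    bad_tf <- setdiff(unlist(lapply(plant, names)), tf_ids)
    if (length(bad_tf)) {
      stop("planting_table references unknown TFs: ",
           paste(bad_tf, collapse = ", "))
    }
  }
  len <- config$promoter_up + config$promoter_down
  L <- config$pwm_length
  bg <- gc_background(config$gc_content)
  modules <- c("core", paste0("module_", 1:10))
  n_orth <- round(config$ortholog_fraction * config$n_genes)

  with_seed(seeds[2], {
    truth_rows <- list(empty_truth())
    human <- vector("list", config$n_genes)
    sites_by_gene <- vector("list", config$n_genes)
    names(sites_by_gene) <- genes
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      seq_chars <- sample(DNA_BASES, len, replace = TRUE, prob = bg)
      placed <- matrix(integer(0), ncol = 2)  # occupied [start0, end0) rows
      site_list <- list()
      wanted <- plant[[g]]
      for (tf in names(wanted)) {
        copies <- wanted[[tf]]
        if (copies == 0) next
        x <- pwms[[match(tf, tf_ids)]]
        for (ci in seq_len(copies)) {
          pos <- NA_integer_
          for (try in seq_len(1000L)) {
            cand <- sample.int(len - L + 1L, 1) - 1L
            if (!any(placed[, 1] < cand + L & placed[, 2] > cand)) {
              pos <- cand
              break
            }
          }
          if (is.na(pos)) {
            stop("cannot place ", copies, " copies of ", tf, " in ", g,
                 " without overlap")
          }
          strand <- sample(c("+", "-"), 1)
          site <- sample_site(x)
          ins <- if (strand == "+") site else revcomp(site)
          seq_chars[(pos + 1L):(pos + L)] <- strsplit(ins, "")[[1]]
          placed <- rbind(placed, c(pos, pos + L))
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            gene_id = g, tf_id = tf, start = pos - config$promoter_up,
            strand = strand, copy = ci, stringsAsFactors = FALSE
          )
          site_list[[length(site_list) + 1L]] <-
            list(pos = pos, seq = ins)
        }
      }
      sites_by_gene[[g]] <- site_list
      human[[gi]] <- promoter_record(
        g, "human", paste(seq_chars, collapse = ""), config$promoter_up, "+",
        ortholog_id = if (gi <= n_orth) mouse_id(g) else NA_character_,
        module_label = modules[(gi - 1L) %% length(modules) + 1L]
      )
    }
    human_truth <- do.call(rbind, truth_rows)

    mouse <- vector("list", n_orth)
    mouse_truth_rows <- list(empty_truth())
    for (gi in seq_len(n_orth)) {
      g <- genes[gi]
      chars <- strsplit(human[[gi]]$sequence, "")[[1]]
      mut <- which(stats::runif(len) < config$substitution_rate)
      for (i in mut) {
        chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
      }
      for (site in sites_by_gene[[g]]) {
        chars[(site$pos + 1L):(site$pos + L)] <- strsplit(site$seq, "")[[1]]
      }
      mouse[[gi]] <- promoter_record(
        mouse_id(g), "mouse", paste(chars, collapse = ""),
        config$promoter_up, "+", ortholog_id = g,
        module_label = human[[gi]]$module_label
      )
      gt <- human_truth[human_truth$gene_id == g, , drop = FALSE]
      if (nrow(gt)) {
        gt$gene_id <- mouse_id(g)
        mouse_truth_rows[[length(mouse_truth_rows) + 1L]] <- gt
      }
    }
    truth <- rbind(human_truth, do.call(rbind, mouse_truth_rows))
    rownames(truth) <- NULL
    list(promoters = c(human, mouse), truth = truth, pwms = pwms)
  })
}

#' Simulate noisy tool reports from planted ground truth
#'
#' The noise channel of the ensemble, applied per species. Each main tool
#' detects every true planting independently with its configured
#' sensitivity and adds Poisson false hits at `tool_fp_rate` per kb
#' (uniform positions, random TF labels and strands). Each supportive tool
#' reports the TFs whose dataset-wide true-hit count exceeds a
#' tool-specific sampled threshold (tool j draws Poisson(j - 1), so the
#' first tool's threshold is always 0), plus false TFs at
#' `supportive_fp_prob`.
#'
#' @param promoters list of `promoter_record` (both species allowed; reports
#'   are generated per species' sub-dataset).
#' @param truth planted ground truth from [generate_promoter_set()].
#' @param config the `simulation_config` (noise parameters and seed).
#' @param tf_ids TF universe for false-hit labels; default: TFs named in
#'   the truth.
#' @return list of `tool_report` (main tools then supportive tools, per
#'   species).
#' @export
simulate_tool_reports <- function(promoters, truth, config, tf_ids = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_main_tools + config$n_supportive_tools < 1) {
    stop("no tools configured")
  }
  gene_ids <- vapply(promoters, `[[`, "", "gene_id")
  if (length(setdiff(truth$gene_id, gene_ids))) {
    stop("ground truth references genes absent from the promoter set")
  }
  if (is.null(tf_ids)) tf_ids <- sort(unique(truth$tf_id))
  L <- config$pwm_length
  seed <- derive_seeds(config$seed, 4)[4]
  species <- vapply(promoters, `[[`, "", "species")

  with_seed(seed, {
    reports <- list()
    for (sp in unique(species)) {
      sp_genes <- gene_ids[species == sp]
      sp_lens <- vapply(promoters[species == sp],
                        function(p) nchar(p$sequence), 0L)
      sp_tss <- vapply(promoters[species == sp],
                       function(p) p$tss_offset, 0L)
      gt <- truth[truth$gene_id %in% sp_genes, , drop = FALSE]
      for (t in seq_len(config$n_main_tools)) {
        sens <- config$tool_sensitivities[t]
        det <- if (nrow(gt)) stats::runif(nrow(gt)) < sens else logical(0)
        hits <- data.frame(
          gene_id = gt$gene_id[det], tf_id = gt$tf_id[det],
          start = gt$start[det], end = gt$start[det] + L,
          strand = gt$strand[det],
          score = round(stats::rnorm(sum(det), 12, 2), 3),
          stringsAsFactors = FALSE
        )
        n_fp <- stats::rpois(length(sp_genes),
                             config$tool_fp_rate * sp_lens / 1000)
        if (sum(n_fp) > 0) {
          gidx <- rep(seq_along(sp_genes), n_fp)
          pos0 <- vapply(sp_lens[gidx] - L + 1L,
                         function(k) sample.int(k, 1) - 1L, 0L)
          fp <- data.frame(
            gene_id = sp_genes[gidx],
            tf_id = sample(tf_ids, sum(n_fp), replace = TRUE),
            start = pos0 - sp_tss[gidx], end = pos0 - sp_tss[gidx] + L,
            strand = sample(c("+", "-"), sum(n_fp), replace = TRUE),
            score = round(stats::rnorm(sum(n_fp), 8, 2), 3),
            stringsAsFactors = FALSE
          )
          hits <- rbind(hits, fp)
        }
        reports[[length(reports) + 1L]] <-
          tool_report(sprintf("main%d", t), "main", species = sp, hits = hits)
      }
      true_counts <- table(gt$tf_id)
      for (t in seq_len(config$n_supportive_tools)) {
        thr <- stats::rpois(1, t - 1)
        found <- names(true_counts)[true_counts > thr]
        fp_tf <- tf_ids[stats::runif(length(tf_ids)) < config$supportive_fp_prob]
        reports[[length(reports) + 1L]] <- tool_report(
          sprintf("supp%d", t), "supportive", species = sp,
          reported_tfs = union(found, setdiff(fp_tf, found))
        )
      }
    }
    reports
  })
}

#' A study-shaped simulation configuration
#'
#' The default synthetic study: 49 human genes with 43 mouse orthologs,
#' -5000/+500 promoter windows, 30 TF motif models, and a tiered planting
#' table — five ubiquitous TFs present in most promoters (the top one with
#' a seven-copy promoter, emulating a strong GC-box-like factor), ten
#' mid-frequency TFs, and fifteen rare TFs. Five main tools at 0.9
#' sensitivity and four supportive tools with 0.2/kb false hits.
#'
#' @param seed master seed (default 1).
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config` with a populated planting table.
#' @export
study_shape_config <- function(seed = 1, ...) {
  genes <- sim_gene_ids(49)
  tfs <- sprintf("TF%02d", 1:30)
  planting <- stats::setNames(
    lapply(genes, function(g) integer(0)), genes)
  plant_seed <- derive_seeds(seed + 1000L, 1)
  with_seed(plant_seed, {
    for (i in 1:5) {                     # ubiquitous tier
      in_genes <- sample(genes, 38 + sample.int(6, 1))
      for (g in in_genes) {
        planting[[g]][tfs[i]] <- sample(1:3, 1)
      }
    }
    planting[["G01"]][tfs[1]] <- 7L      # one seven-copy promoter
    for (i in 6:15) {                    # mid tier
      in_genes <- sample(genes, 14 + sample.int(10, 1))
      for (g in in_genes) {
        planting[[g]][tfs[i]] <- sample(1:2, 1)
      }
    }
    for (i in 16:30) {                   # rare tier
      in_genes <- sample(genes, 1 + sample.int(6, 1))
      for (g in in_genes) {
        planting[[g]][tfs[i]] <- 1L
      }
    }
  })
  simulation_config(planting_table = planting, seed = seed, ...)
}
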