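# Pipeline driver: generate -> detect -> metrics -> patterns -> features,
# steered by one declarative config, with a reproducibility manifest.

digest_file <- function(path) unname(tools::md5sum(path))

digest_obj <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2L, compress = FALSE)
  digest_file(tmp)
}

write_tsv <- function(df, path, header_comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comments) writeLines(paste0("# ", h), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Validate a pipeline configuration
#'
#' @param config list (or YAML path) with `output_dir`, `seed`, `mode`
#'   (`"mc"` or `"planted"`), `composition` (arguments of
#'   [build_composition()]), optional `generator`, `planted`, `analysis`
#'   ([analysis_config()] overrides), `label`, and `stages`.
#' @return the normalized config list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config needs an output_dir")
  if (is.null(config$composition)) stop("config needs a composition block")
  need <- c("n_peptide", "n_drug", "drug_charge", "n_zn")
  miss <- setdiff(need, names(config$composition))
  if (length(miss))
    stop("composition block lacks: ", paste(miss, collapse = ", "))
  config$mode <- match.arg(config$mode %||% "mc", c("mc", "planted"))
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||%
    c("generate", "detect", "metrics", "patterns", "features")
  bad <- setdiff(config$stages,
                 c("generate", "detect", "metrics", "patterns", "features"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config$analysis <- do.call(analysis_config,
                             c(config$analysis %||% list(),
                               list(rng_seed = config$seed)))
  config
}

#' Run the co-assembly analysis pipeline
#'
#' Executes the requested stages in order: `generate` (synthetic trajectory:
#' Monte Carlo co-assembly or planted clusters), `detect` (contact-graph
#' clusters per frame), `metrics` (per-cluster statistics and size-binned
#' profiles), `patterns` (pairwise, triplet and chemical-group interaction
#' profiles) and `features` (per-cluster SVM feature vectors). Every output
#' is written under `output_dir` and recorded, with an md5 digest, in
#' `manifest.json`. A stage whose inputs and configuration are unchanged
#' since the previous run is skipped.
#'
#' @param config list or YAML path, see [validate_pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  manifest_path <- out("manifest.json")
  prev <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL

  composition <- do.call(build_composition, cfg$composition)
  templates <- default_templates(drug_charge = composition$drug_charge,
                                 drug_name = composition$drug_name)
  acfg <- cfg$analysis
  manifest <- list(tool = "coassembly",
                   version = as.character(utils::packageVersion("coassembly")),
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "analysis")],
                   analysis = unclass(acfg),
                   stages = list())
  state <- new.env(parent = emptyenv())

  stage_key <- function(name, inputs) digest_obj(list(name, inputs, cfg$seed))
  record <- function(name, key, outputs, t0, skipped = FALSE) {
    manifest$stages[[name]] <<- list(
      key = key, skipped = skipped,
      seconds = round(as.numeric(Sys.time()) - t0, 3),
      outputs = lapply(outputs, function(p)
        list(path = p, md5 = digest_file(p))))
  }
  can_skip <- function(name, key, outputs) {
    !is.null(prev) && !is.null(prev$stages[[name]]) &&
      identical(prev$stages[[name]]$key, key) &&
      all(file.exists(unlist(outputs)))
  }

  load_frames <- function() {
    if (is.null(state$frames)) {
      map <- load_component_map(out("map.yml"))
      state$frames <- read_multimodel_pdb(out("traj.pdb"), map)
    }
    state$frames
  }
  load_clusters <- function() {
    if (is.null(state$clusters)) {
      frames <- load_frames()
      state$clusters <- unlist(lapply(seq_along(frames), function(m)
        detect_clusters(frames[[m]], acfg$contact_cutoff, m)),
        recursive = FALSE)
    }
    state$clusters
  }
  filtered_clusters <- function() {
    cl <- load_clusters()
    keep <- filter_clusters(cl, acfg$min_cluster_size)
    if (!length(keep)) cl else keep
  }

  for (stage in cfg$stages) {
    t0 <- as.numeric(Sys.time())
    if (stage == "generate") {
      key <- stage_key("generate", cfg[c("mode", "composition", "generator",
                                         "planted")])
      outs <- list(out("traj.pdb"), out("map.yml"))
      if (can_skip("generate", key, outs)) {
        record("generate", key, outs, t0, skipped = TRUE)
        next
      }
      if (cfg$mode == "mc") {
        gen <- cfg$generator %||% list()
        aff <- drug_affinity_preset(gen$affinity_class %||% "no3_affine",
                                    gen$drug_strength %||% 3.5)
        frames <- generate_mc_trajectory(
          composition, templates, aff,
          n_sweeps = gen$n_sweeps %||% 200L,
          sample_every = gen$sample_every %||% 20L,
          kT = gen$kT %||% 1.0, seed = cfg$seed)
      } else {
        pl <- cfg$planted %||% list()
        ccs <- lapply(pl$clusters %||% list(), unlist)
        frames <- list(generate_planted_configuration(
          composition, templates, ccs, seed = cfg$seed,
          cutoff = acfg$contact_cutoff)$frame)
      }
      state$frames <- frames
      write_multimodel_pdb(frames, out("traj.pdb"))
      map <- component_map_from_templates(templates, composition$box_length,
                                          acfg)
      write_component_map(map, out("map.yml"))
      record("generate", key, outs, t0)
    } else if (stage == "detect") {
      key <- stage_key("detect", list(digest_file(out("traj.pdb")),
                                      acfg$contact_cutoff))
      outs <- list(out("clusters.tsv"))
      if (can_skip("detect", key, outs)) {
        record("detect", key, outs, t0, skipped = TRUE)
        next
      }
      tab <- clusters_table(load_clusters())
      write_tsv(tab, out("clusters.tsv"),
                sprintf("contact_cutoff=%.3f min_cluster_size=%d (unfiltered export)",
                        acfg$contact_cutoff, acfg$min_cluster_size))
      record("detect", key, outs, t0)
    } else if (stage == "metrics") {
      key <- stage_key("metrics", list(digest_file(out("traj.pdb")),
                                       unclass(acfg)))
      outs <- list(out("stats.tsv"), out("profiles.tsv"))
      if (can_skip("metrics", key, outs)) {
        record("metrics", key, outs, t0, skipped = TRUE)
        next
      }
      frames <- load_frames()
      cl <- filtered_clusters()
      stats <- do.call(rbind, lapply(cl, function(c1)
        cluster_stats(frames[[c1$frame_index]], c1, composition$n_drug,
                      acfg)))
      state$stats <- stats
      state$stat_clusters <- cl
      write_tsv(stats, out("stats.tsv"),
                sprintf("probe_radius=%.2f sasa_points=%d",
                        acfg$probe_radius, acfg$sasa_points))
      write_tsv(size_binned_profiles(stats, cfg$bin_width %||% 10L),
                out("profiles.tsv"),
                sprintf("bin_width=%d", cfg$bin_width %||% 10L))
      record("metrics", key, outs, t0)
    } else if (stage == "patterns") {
      key <- stage_key("patterns", list(digest_file(out("traj.pdb")),
                                        acfg$contact_cutoff,
                                        acfg$min_cluster_size))
      outs <- list(out("patterns.tsv"))
      if (can_skip("patterns", key, outs)) {
        record("patterns", key, outs, t0, skipped = TRUE)
        next
      }
      frames <- load_frames()
      cl <- filtered_clusters()
      trip <- ensemble_triplet_profile(cl)
      pw <- pairwise_profile(cl)
      med <- mediation_by_ions(cl)
      gc_counts <- do.call(rbind, lapply(seq_along(frames), function(m) {
        clm <- cl[vapply(cl, `[[`, 0L, "frame_index") == m]
        if (!length(clm)) return(NULL)
        group_contact_profile(frames[[m]], clm, acfg$contact_cutoff)$counts
      }))
      rows <- rbind(
        data.frame(table_name = "triplet", label = names(trip),
                   value = as.numeric(trip), stringsAsFactors = FALSE),
        data.frame(table_name = "pair", label = names(pw$pair_probability),
                   value = as.numeric(pw$pair_probability),
                   stringsAsFactors = FALSE),
        data.frame(table_name = "mediation", label = names(med),
                   value = as.numeric(med), stringsAsFactors = FALSE))
      if (!is.null(gc_counts) && nrow(gc_counts)) {
        agg <- stats::aggregate(count ~ source_group + partner, gc_counts, sum)
        agg <- do.call(rbind, lapply(split(agg, agg$source_group), function(d) {
          d$prob <- d$count / sum(d$count); d
        }))
        rows <- rbind(rows, data.frame(
          table_name = "group_contact",
          label = paste(agg$source_group, agg$partner, sep = ">"),
          value = agg$prob, stringsAsFactors = FALSE))
      }
      write_tsv(rows, out("patterns.tsv"),
                sprintf("contact_cutoff=%.3f", acfg$contact_cutoff))
      record("patterns", key, outs, t0)
    } else if (stage == "features") {
      key <- stage_key("features", list(digest_file(out("traj.pdb")),
                                        unclass(acfg), cfg$label))
      outs <- list(out("features.tsv"))
      if (can_skip("features", key, outs)) {
        record("features", key, outs, t0, skipped = TRUE)
        next
      }
      frames <- load_frames()
      cl <- filtered_clusters()
      if (is.null(state$stats) ||
          length(state$stat_clusters %||% list()) != length(cl)) {
        state$stats <- do.call(rbind, lapply(cl, function(c1)
          cluster_stats(frames[[c1$frame_index]], c1, composition$n_drug,
                        acfg)))
        state$stat_clusters <- cl
      }
      profiles <- lapply(cl, mediated_triplets)
      labels <- if (!is.null(cfg$label)) rep(cfg$label, length(cl)) else NULL
      feats <- assemble_features(state$stats, profiles, labels)
      write_tsv(feats, out("features.tsv"),
                sprintf("label=%s", cfg$label %||% "unlabeled"))
      record("features", key, outs, t0)
    }
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}
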