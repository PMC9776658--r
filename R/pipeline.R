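#' Prepare model-ready samples from labeled clips
#'
#' Runs the full preprocessing chain on a set of labeled clips: every frame
#' is converted to a canonical 128 x 128 grayscale frame, overlapping
#' 16-frame windows are enumerated per clip, and each window is reduced by
#' two-level fusion to a 128 x 128 x 3 x 4 sample array.
#'
#' @param clips Named list of labeled `raw_clip` objects (or the list
#'   returned by [make_dataset()]).
#' @param spec A [window_spec()].
#' @param verbose Print one line per clip.
#' @return List with `samples` (list of H x W x 3 x 4 arrays) and `records`
#'   (data frame of window records; one row per sample).
#' @export
#' @examples
#' \donttest{
#' ds <- make_dataset(scene_config(n_clips_per_class = 1,
#'                                 frame_count_range = c(21, 21)))
#' prep <- prepare_samples(ds$clips)
#' length(prep$samples); nrow(prep$records)
#' }
prepare_samples <- function(clips, spec = window_spec(), verbose = FALSE) {
  if (!is.null(clips$clips)) clips <- clips$clips
  samples <- list()
  records <- list()
  for (clip in clips) {
    recs <- enumerate_windows(clip, spec)
    if (nrow(recs) == 0) next
    gray <- lapply(clip$frames, to_gray_frame)
    for (r in seq_len(nrow(recs))) {
      stack <- two_level_fuse(window_frames(gray, recs[r, ]))
      samples[[length(samples) + 1]] <- stack_to_array(stack)
    }
    records[[length(records) + 1]] <- recs
    if (verbose)
      message(sprintf("clip %s: %d windows", clip$source_id, nrow(recs)))
  }
  if (length(samples) == 0)
    stop_input("no clip produced a complete window")
  list(samples = samples, records = do.call(rbind, records))
}

#' Preprocess clip directories into fused-stack PNGs
#'
#' Disk-based variant of [prepare_samples()]: loads every clip directory
#' under `in_dir` (written by [make_dataset()] or [write_clip()]), fuses its
#' windows and writes them with [write_fused_stack()] plus a combined window
#' manifest.
#'
#' @param in_dir Directory of clip subdirectories.
#' @param out_dir Output directory for fused PNGs and `windows.json`.
#' @param spec A [window_spec()].
#' @return The window manifest data frame, invisibly.
#' @export
preprocess_dir <- function(in_dir, out_dir, spec = window_spec()) {
  dirs <- list.dirs(in_dir, recursive = FALSE)
  if (length(dirs) == 0) stop_input("no clip directories under ", in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_recs <- list()
  for (d in dirs) {
    clip <- load_clip(d)
    recs <- enumerate_windows(clip, spec)
    if (nrow(recs) == 0) next
    gray <- lapply(clip$frames, to_gray_frame)
    for (r in seq_len(nrow(recs))) {
      stack <- two_level_fuse(window_frames(gray, recs[r, ]))
      write_fused_stack(stack, out_dir, recs$clip_id[r],
                        recs$window_index[r], label = recs$label[r],
                        frame_range = c(recs$start[r], recs$end[r]))
    }
    all_recs[[length(all_recs) + 1]] <- recs
  }
  manifest <- do.call(rbind, all_recs)
  write_manifest(manifest, file.path(out_dir, "windows.json"))
  invisible(manifest)
}
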