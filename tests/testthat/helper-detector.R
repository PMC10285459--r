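# shared detector evaluation helper: run detection over a dataset
# directory and return AP at IoU 0.5
dataset_ap50 <- function(model, dir) {
  recs <- read_annotation_dir(dir)
  dets <- list()
  for (r in recs)
    dets[[r$image_id]] <- suppressWarnings(
      detect(file.path(dir, paste0(r$image_id, ".png")), model))
  evaluate(recs, dets, thresholds = 0.5, criteria = "iou",
           subsets = FALSE)$ap$ap[1]
}
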