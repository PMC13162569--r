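# colposeg

Dataset curation and evaluation toolkit for multi-class segmentation of
colposcopy images.

Expert-annotated colposcopy datasets are built from brush masks drawn in
annotation platforms such as CVAT and consumed by per-class segmentation
models. Between the export and the model sits a surprising amount of
delicate data engineering: decoding run-length-encoded (RLE) masks,
turning annular structures (squamous epithelium ringing the external os —
the "donut-shape" problem) into single simple polygons, splitting
multi-component findings into independent instances, filtering unusable
images and minority resolutions, injecting background images, and
splitting data without leakage. `colposeg` implements that pipeline, plus
the evaluation stack used to compare segmentation models, as a reusable R
package. The neural models themselves are external: the package reads
their predictions as COCO-style result JSON.

## What it computes

Pixel-level metrics compare a predicted mask against a reference mask via
pixel counts TP, FP, FN, with ε = 10⁻⁸ guarding empty denominators:

    Dice      = 2·TP / (2·TP + FP + FN + ε)
    IoU       =   TP / (TP + FP + FN + ε)
    Precision =   TP / (TP + FP + ε)
    Recall    =   TP / (TP + FN + ε)

Per-class results are reported as **mean (median) ± SD** over per-image
records. Instance-level quality uses mask **mAP50-95** (greedy
confidence-ordered matching, 101-point interpolated AP averaged over IoU
thresholds 0.50–0.95) and instance **F1** at IoU 0.5, combined into the
hyperparameter-tuning objective

    objective = 0.7 · F1 + 0.3 · mAP50-95

## Modules

| Area | Functions |
| --- | --- |
| Annotation I/O | `parse_cvat_xml()`, `write_cvat()`, `parse_coco()`, `write_coco()`, `read_predictions()` |
| RLE codec | `rle_encode()`, `rle_decode()` (CVAT bounding-box, COCO uncompressed/compressed) |
| Mask geometry | `extract_contours()`, `simplify_contour()`, `filter_small()`, `merge_donut()`, `split_components()`, `normalize_polygon()`, `rasterize()`, `vectorize_mask()` |
| Dataset building | `filter_images()`, `build_class_dataset()`, `split_dataset()`, `export_yolo_labels()`, `export_coco()` |
| Evaluation | `pixel_confusion()`, `dice()`, `iou()`, `precision()`, `recall()`, `evaluate_image()`, `evaluate_set()`, `summarize_metrics()`, `mask_map()`, `instance_f1()`, `composite_objective()` |
| Synthetic fixtures | `generate_scene()`, `generate_scene_set()`, `perturb_predictions()` |
| CLI | `run_cli()` and `inst/cli/colposeg` (`convert`, `build`, `evaluate`, `synth`) |

## Worked example

```r
library(colposeg)

# a seeded synthetic scene: elliptical cervix, ring epithelium (donut),
# thin instrument, multi-component lesion
sc  <- generate_scene(default_scene_spec(seed = 7))
set <- sc$set
sc$pixel_counts
#>                Cervix   Squamous epithelium   Medical instruments   Acetowhite epithelium
#>                  7672                  2160                    96                     432

# donut handling: ring mask -> one simple polygon -> back to pixels, exactly
im   <- set$images[[1]]
ring <- rle_decode(im$shapes[[2]]$payload, im$width_px, im$height_px)
poly <- vectorize_mask(ring, im$width_px, im$height_px)[[1]]
sum(rasterize(poly, im$width_px, im$height_px) != ring)
#> [1] 0

# evaluate perturbed predictions
preds <- perturb_predictions(set, perturb_spec(seed = 1, shift = c(3, 0)))
rec   <- evaluate_image(preds, im$shapes, "Cervix", im$image_id,
                        im$width_px, im$height_px)
round(rec$dice, 3)
#> [1] 0.928

composite_objective(1, 0)
#> [1] 0.7
```

A 10-image dataset splits 7 / 2 / 1 under the default 70/20/10 proportions:

```r
man <- split_dataset(generate_scene_set(10, seed = 44), seed = 0)
table(man$assignment)
#> test train   val
#>    1     7     2
```

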