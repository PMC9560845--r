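# mhanet

Binary segmentation of medical images — retinal vessels in fundus
photographs, stent wires in X-ray fluoroscopy, polyps in colonoscopy — with
a **multibranch hybrid attention network (MHA-Net)**: a U-Net-style
encoder/decoder in which

* the encoder is a **ResNet-34** feature extractor exposing five skip taps
  at strides 2/4/8/16/32 with 64/64/128/256/512 channels;
* a **pyramid split attention (PSA)** module bridges the stride-32
  bottleneck: the 512 channels are split into 4 groups of 128, each group
  is convolved at its own kernel scale (3/5/7/9, with group-convolution
  counts 1/4/8/16), weighted by a squeeze-excitation (SE) vector, and the
  group weights are renormalised with a softmax across the group axis at
  every channel position;
* each **MHA decoder stage** upsamples by a stride-2 transposed
  convolution, concatenates the matching encoder tap, applies two 3×3
  convolutions (BN + ReLU), SE channel attention, and finally **adds the
  skip tap a second time** (summation branch); a skip-free stage then
  brings the stride-2 features to full resolution for a two-convolution
  segmentation head with sigmoid output.

Training uses binary cross-entropy on logits with Adam (default learning
rate 1e-4, per-dataset presets for batch size and epochs), and evaluation
covers the standard pixel-overlap suite

```
DC  = 2TP/(2TP+FP+FN)     IR = IoU_poly = TP/(TP+FP+FN)
Rec = TP/(TP+FN)          Spec = TN/(TN+FP)       Prec = TP/(TP+FP)
IoU_bg = TN/(TN+FP+FN)    mIoU = (IoU_poly+IoU_bg)/2
Ac  = (TP+TN)/N           AUC  (rank/trapezoidal ROC)
```

Everything runs on the CPU: the convolution forward/backward passes are
compiled im2col/GEMM kernels (RcppArmadillo) inside the package, so no
external deep-learning runtime is needed. A deterministic synthetic-fixture
generator (curvilinear vessels, wire lattices, deformed-ellipse polyps)
makes every stage of the pipeline testable without downloading any dataset.

## Worked example

```r
library(mhanet)

# the full-scale network reproduces the published feature-map arithmetic
model <- assemble_mhanet(model_config(input_size = c(800, 800)))
count_parameters(model) / 1e6
#> [1] 33.65994
str(trace_shapes(model)[c("bottleneck", "stage1_concat", "prehead")])
#> $ bottleneck   : int [1:4]  25  25 512   1
#> $ stage1_concat: int [1:4]  50  50 768   1
#> $ prehead      : int [1:4] 800 800  32   1

# desk-scale training on synthetic polyp-style blobs (quarter widths)
spec <- synthetic_spec(c(96, 96), "polyp")
ds <- generate_dataset(spec, 48, seed = 101)
small <- assemble_mhanet(model_config(width_mult = 0.25,
                                      input_size = c(96, 96), seed = 7))
fit <- train(small, ds[1:40], val_set = ds[41:48],
             train_config(learning_rate = 1e-3, batch_size = 4, epochs = 30,
                          seed = 7))
evaluate(fit$model, ds[41:48])$aggregate
#> dc=0.9256  ir=0.8625  rec=0.8630  spec=1.0000  prec=0.9992  ioup=0.8625
#> ioub=0.9882  miou=0.9254  ac=0.9891  se=0.8630  auc=0.9999
```

The aggregate report reads as: Dice 0.926 — the predicted and true polyp
masks overlap to 93% of their mean size on held-out samples; foreground IoU
0.86; background IoU 0.99; pixel accuracy 0.989; the ROC over raw
probabilities is essentially perfect (AUC 0.9999). A command-line front end
wraps the same functions:

```sh
mhanet=$(Rscript -e 'cat(system.file("exec", "mhanet.R", package = "mhanet"))')
Rscript $mhanet synth --style polyp --n 100 --size 96 --out data/
Rscript $mhanet train --config run.yaml --data data/ --out run/
Rscript $mhanet predict --checkpoint run/checkpoint.rds --image img.png --out pred
```

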