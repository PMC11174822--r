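# chanattn

Cross-channel patch-wise attention networks for multi-channel sensor
time series, in R.

## The problem

Wearable and physiological recordings — IMU windows from a phone, EEG/EOG
epochs from polysomnography — arrive as fixed-rate signal windows
`X ∈ R^{C×L}` whose channel count `C` and length `L` differ from device to
device. Ordinary convolutional classifiers bind their first layer to `C`,
so a network pretrained on one sensor layout cannot be reused on another
without rebuilding and retraining early layers, which is exactly where the
transferable local features live.

`chanattn` implements an adaptive attention-convolution architecture whose
trunk holds **no channel-specific weights**: the same trained model accepts
3, 4 or 8 input channels unchanged, and moving to a new task (even a new
sensor modality or class count) means replacing only the final
classification layer.

## The model

1. **Spectrogram conversion.** Each channel is converted to a
   log-magnitude STFT spectrogram (Hann window, 50% overlap), resized to
   `H×W` (default 48×48) by bilinear interpolation and min-max normalized,
   giving a stack `S ∈ R^{C×H×W}`.
2. **Adaptive convolution trunk** (3 stacked attention iterations).
   At each iteration, 1×1 convolutions over the head axis project the
   input into query/key/value head tensors (`Q,K,V ∈ R^{C×M×H×W}`; a
   double-layer block expands the single input head at the first
   iteration). A small *attention kernel* (default 2×2) slides over every
   head's map, unfolding it into patches `(C, Patch_Size, B)` where
   `B = ∏_d ⌊(size_d − kernel_d)/stride + 1⌋`. For every patch group `b`,
   channels attend to each other:

   `A(i,j)_b = softmax_j [ sigmoid(q_i)_b · (k_j)_b ]`,
   `out(i)_b = Σ_j A(i,j)_b (v_j)_b`,

   after which patches are folded back to maps and adaptive average
   pooling reaches the next stage's target shape. The default schedule is
   64 → 128 → 256 heads with maps 48² → 24² → 12²; the final iteration
   permutes channels ahead of the pool and squeezes `(C,H,W)` into a
   per-head global average, producing a 256-vector regardless of `C`.
3. **Head-importance gating.** A fully connected layer plus sigmoid gates
   each of the 256 head features: `V = σ(W v_mh + b) ⊙ v_mh`.
4. **Classifier.** A two-layer MLP (ReLU, then softmax) trained with
   cross-entropy.

Heads are generated and mixed by 1×1 convolutions over the head axis
rather than by the standard concat + feed-forward map, which keeps the
default model at **830,216 trainable parameters (~0.83 M, a ~3.2 MB
float32 checkpoint)**; a `"standard"` comparator mode exists for the
ablation.

## Worked example

```r
library(chanattn)

# three-channel synthetic windows, 1024 samples at 100 Hz, 3 classes
spec    <- synth_spec(n_windows = 6, seed = 42)
windows <- generate_windows(spec)
windows[[1]]
#> <mc_window: 3 channels x 1024 samples @ 100 Hz, label 0>

stacks <- convert_batch(windows, target_size = 16)
dim(stacks[[1]])
#> [1]  3 16 16

cfg   <- model_config(spec_size = 16, heads = c(8, 16, 32),
                      hidden = 128, n_classes = 3)
model <- build_model(cfg, seed = 1)
model
#> <attn_model: 7,995 params (trunk 7,608)>
#> <model_config: 16x16 spectrograms, kernel 2x2 stride 2,
#>   heads 8/16/32, hidden 128, 3 classes, gate on, multihead conv>

fw <- predict_window(model, stacks[[1]])
round(fw$probs, 3)
#> [1] 0.333 0.332 0.336     # untrained: near-uniform over the 3 classes
length(fw$vmh)
#> [1] 32                    # feature vector = final head count
```

Training, evaluation and transfer:

```r
ds  <- windows_to_dataset(generate_windows(synth_spec(seed = 7)), target_size = 16)
fit <- train_model(model, ds, train_config(epochs = 35, batch_size = 24, seed = 7))
evaluate_model(fit$model, ds)$accuracy

# reuse the trunk on a dataset with a different channel count
save_checkpoint(fit$model, "trunk.ckpt")
ft <- fine_tune("trunk.ckpt", new_dataset, n_classes = 3)   # lr defaults to 1e-4
```

The default (48×48, 8-class) configuration is built with `model_config()`
and reproduces the reference size figures:

```r
count_parameters(build_model(model_config()))
#> [1] 830216
```

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "chanattn", package = "chanattn"))')
Rscript $CLI synth  --out data.mcsc --seed 7
Rscript $CLI train  --data data.mcsc --config cfg.yaml --out model.ckpt
Rscript $CLI evaluate --ckpt model.ckpt --data data.mcsc
Rscript $CLI params --ckpt model.ckpt
```

`--config` takes a YAML file with `model:` and `train:` sections mirroring
`model_config()` / `train_config()` arguments.

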