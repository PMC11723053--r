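#!/usr/bin/env python
"""Convert a public motor-imagery recording into a mieog bundle.

Requires network access plus the `mne` and `moabb` packages (not needed by
the R package itself). Epoch windows follow the package conventions:
seconds 2-6 of each trial for the 4-class competition dataset (1000
samples at 250 Hz) and seconds 3-7 for the 7-class dataset (800 samples at
200 Hz). The trailing channels are tagged EOG (3 and 2 respectively).

Usage:
    python fetch_public_dataset.py --dataset bci_iv_2a --subject 1 --out cache/
"""
import argparse
import gzip
import json
import pathlib

import numpy as np

SPECS = {
    "bci_iv_2a": dict(moabb="BNCI2014_001", n_eog=3, sfreq=250.0,
                      tmin=2.0, tmax=6.0),
    "weibo_2014": dict(moabb="Weibo2014", n_eog=2, sfreq=200.0,
                       tmin=3.0, tmax=7.0),
}


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--dataset", choices=sorted(SPECS), required=True)
    ap.add_argument("--subject", type=int, required=True)
    ap.add_argument("--out", required=True)
    args = ap.parse_args()
    spec = SPECS[args.dataset]

    import moabb.datasets
    from moabb.paradigms import MotorImagery

    dataset = getattr(moabb.datasets, spec["moabb"])()
    paradigm = MotorImagery(tmin=spec["tmin"], tmax=spec["tmax"],
                            fmin=0.01, fmax=spec["sfreq"] / 2.0 - 0.01,
                            channels=None, resample=None)
    x, labels, meta = paradigm.get_data(dataset, subjects=[args.subject],
                                        return_epochs=False)
    classes = sorted(set(labels))
    y = np.array([classes.index(l) for l in labels], dtype=int)
    n_trials, n_channels, n_samples = x.shape
    names = [f"EEG{i}" for i in range(n_channels - spec["n_eog"])] + \
        [f"EOG{i}" for i in range(spec["n_eog"])]
    modal = ["EEG"] * (n_channels - spec["n_eog"]) + ["EOG"] * spec["n_eog"]

    out = pathlib.Path(args.out) / f"{args.dataset}_subject{args.subject:02d}"
    out.mkdir(parents=True, exist_ok=True)
    # column-major (trials fastest), little-endian doubles, to match readBin
    arr = np.asfortranarray(x * 1e6)  # volts -> microvolts
    with gzip.open(out / "data.bin.gz", "wb") as fh:
        fh.write(arr.astype("<f8").tobytes(order="F"))
    meta_json = dict(format="mieog-bundle", version=1,
                     dim=[n_trials, n_channels, n_samples],
                     labels=y.tolist(), class_names=classes,
                     channel_names=names, channel_modalities=modal,
                     sampling_rate=spec["sfreq"],
                     subject_id=f"S{args.subject}")
    (out / "meta.json").write_text(json.dumps(meta_json))
    print(f"wrote {out}: {x.shape}, classes {classes}")


if __name__ == "__main__":
    main()
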