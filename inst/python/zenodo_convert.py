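#!/usr/bin/env python
"""Convert a MATLAB virtual-population container to the pwva CSV layout.

Usage: zenodo_convert.py <container.mat> <mapping.json> <out_dir>

The container schema is described entirely by the mapping file; this script
only walks struct-field chains, converts pressures to Pa and writes the
CSV + manifest layout read by pwva::load_population(format="synthetic_csv").
"""
import json
import os
import sys

import numpy as np
import scipy.io as sio

MMHG_PA = 133.322


def get_chain(obj, chain):
    for key in chain.split("/"):
        if isinstance(obj, dict):
            obj = obj[key]
        else:
            obj = getattr(obj, key)
    return obj


def as_vec(x):
    return np.asarray(x, dtype=float).ravel()


def main(mat_path, map_path, out_dir):
    with open(map_path) as fh:
        mp = json.load(fh)
    mat = sio.loadmat(mat_path, squeeze_me=True, struct_as_record=False)
    subjects = np.atleast_1d(get_chain(mat, mp["subjects_array"]))
    os.makedirs(out_dir, exist_ok=True)
    entries = []
    for i, sub in enumerate(subjects):
        sid = "s%04d" % (i + 1)
        fs = float(get_chain(sub, mp["fs"]))
        waves = {}
        for key, chain in mp["waves"].items():
            site, modality = key.split(".")
            try:
                y = as_vec(get_chain(sub, chain))
            except (KeyError, AttributeError):
                continue  # absent signal: subject stays, index degrades
            if modality == "pressure" and mp.get("pressure_unit") == "mmHg":
                y = y * MMHG_PA
            fn = "%s_%s_%s.csv" % (sid, site, modality)
            t = np.arange(y.size) / fs
            with open(os.path.join(out_dir, fn), "w") as fh:
                fh.write("# site: %s\n# modality: %s\n# fs: %.17g\nt,value\n"
                         % (site, modality, fs))
                for ti, yi in zip(t, y):
                    fh.write("%.17g,%.17g\n" % (ti, yi))
            waves[key] = fn
        geo = mp["geometry"]
        segs = np.atleast_1d(get_chain(sub, geo["aortic_segments"]))
        aortic_path = [
            dict(length=float(get_chain(s, geo["segment_length"])),
                 r_in=float(get_chain(s, geo["segment_r_in"])),
                 r_out=float(get_chain(s, geo["segment_r_out"])),
                 k1=float(get_chain(s, geo["k1"])),
                 k2=float(get_chain(s, geo["k2"])),
                 k3=float(get_chain(s, geo["k3"])),
                 h_over_r=float(geo["h_over_r"]))
            for s in segs]
        entries.append(dict(
            id=sid,
            age=float(get_chain(sub, mp["fields"]["age"])),
            height=float(get_chain(sub, mp["fields"]["height"])),
            rho=float(get_chain(sub, mp["fields"]["rho"])),
            aortic_path=aortic_path,
            path_lengths={k: float(get_chain(sub, v))
                          for k, v in mp["path_lengths"].items()},
            waves=waves,
            truth=None))
    with open(os.path.join(out_dir, "manifest.json"), "w") as fh:
        json.dump(dict(format="pwva_population", version=1,
                       subjects=entries), fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], sys.argv[3])
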