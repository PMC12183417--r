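"""Minimal HDF5 <-> raw-binary bridge used by the R package.

Complex datasets are exchanged as C-order float64 binaries with
interleaved real/imaginary parts plus a JSON header describing the shape.
Invoked as:
    h5bridge.py read  <h5file> <dataset> <binfile> <metafile>
    h5bridge.py write <h5file> <dataset> <binfile> <metafile>
    h5bridge.py info  <h5file> <metafile>
"""
import json
import sys

import h5py
import numpy as np


def die(msg):
    sys.stderr.write(msg + "\n")
    sys.exit(1)


def read(path, dataset, binfile, metafile):
    with h5py.File(path, "r") as f:
        if dataset not in f:
            die("dataset '%s' not found in %s" % (dataset, path))
        ds = f[dataset]
        if ds.dtype.kind != "c":
            die("dataset '%s' is not complex (dtype %s)" % (dataset, ds.dtype))
        arr = np.asarray(ds[...], dtype=np.complex128)
        attrs = {k: (v.tolist() if hasattr(v, "tolist") else v)
                 for k, v in ds.attrs.items()}
    view = arr.view(np.float64)  # interleaved re/im, C order
    view.tofile(binfile)
    with open(metafile, "w") as fh:
        json.dump({"shape": list(arr.shape), "attrs": attrs}, fh)


def write(path, dataset, binfile, metafile):
    with open(metafile) as fh:
        meta = json.load(fh)
    shape = tuple(meta["shape"])
    raw = np.fromfile(binfile, dtype=np.float64)
    arr = raw.view(np.complex128).reshape(shape)
    with h5py.File(path, "a") as f:
        if dataset in f:
            del f[dataset]
        ds = f.create_dataset(dataset, data=arr, track_times=False)
        for k, v in meta.get("attrs", {}).items():
            ds.attrs[k] = v


def info(path, metafile):
    with h5py.File(path, "r") as f:
        out = {}
        for name, ds in f.items():
            if isinstance(ds, h5py.Dataset):
                out[name] = {"shape": list(ds.shape), "dtype": str(ds.dtype)}
    with open(metafile, "w") as fh:
        json.dump(out, fh)


def main(argv):
    if len(argv) < 3:
        die("usage: h5bridge.py read|write|info ...")
    mode = argv[1]
    if mode == "read":
        read(*argv[2:6])
    elif mode == "write":
        write(*argv[2:6])
    elif mode == "info":
        info(*argv[2:4])
    else:
        die("unknown mode: " + mode)


if __name__ == "__main__":
    main(sys.argv)
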