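"""Minimal SNIRF (HDF5) writer/reader used by nirsdot::export_snirf().

Called as:  python snirf_io.py write <payload.json>
            python snirf_io.py read  <file.snirf> <out.json>

The payload JSON carries the time vector, the stacked (wavelength-block)
data matrix, probe geometry and the per-channel source/detector indices.
"""
import json
import sys

import h5py
import numpy as np


def _str(group, name, value):
    group.create_dataset(name, data=np.bytes_(value))


def write(payload_path):
    with open(payload_path) as fh:
        p = json.load(fh)
    data = np.asarray(p["data"], dtype=float)          # (2P) x N
    time = np.asarray(p["time"], dtype=float)
    wavelengths = np.asarray(p["wavelengths"], dtype=float)
    src = np.asarray(p["source_idx"], dtype=int)
    det = np.asarray(p["detector_idx"], dtype=int)
    n_ch = len(src)

    with h5py.File(p["path"], "w") as f:
        _str(f, "formatVersion", "1.0")
        nirs = f.create_group("nirs")
        d1 = nirs.create_group("data1")
        # SNIRF stores time x measurement
        d1.create_dataset("dataTimeSeries", data=data.T)
        d1.create_dataset("time", data=time)
        for i in range(data.shape[0]):
            wl_index = i // n_ch + 1
            ml = d1.create_group("measurementList%d" % (i + 1))
            ml.create_dataset("sourceIndex", data=int(src[i % n_ch]))
            ml.create_dataset("detectorIndex", data=int(det[i % n_ch]))
            ml.create_dataset("wavelengthIndex", data=wl_index)
            ml.create_dataset("dataType", data=1)      # CW amplitude
            ml.create_dataset("dataTypeIndex", data=1)
        probe = nirs.create_group("probe")
        probe.create_dataset("wavelengths", data=wavelengths)
        probe.create_dataset("sourcePos3D",
                             data=np.asarray(p["source_pos"], dtype=float))
        probe.create_dataset("detectorPos3D",
                             data=np.asarray(p["detector_pos"], dtype=float))


def read(path, out_path):
    with h5py.File(path, "r") as f:
        d1 = f["nirs/data1"]
        out = {
            "data": np.asarray(d1["dataTimeSeries"]).T.tolist(),
            "time": np.asarray(d1["time"]).tolist(),
            "wavelengths": np.asarray(f["nirs/probe/wavelengths"]).tolist(),
        }
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    if sys.argv[1] == "write":
        write(sys.argv[2])
    elif sys.argv[1] == "read":
        read(sys.argv[2], sys.argv[3])
    else:
        sys.exit("unknown mode: " + sys.argv[1])
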