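"""Convert a DICOM series directory to a thyrosweep manifest directory.

Usage: python dicom_to_manifest.py <dicom_dir> <out_dir>

Frames are ordered by InstanceNumber (filename as fallback) and written as
8-bit grey PNGs. Tracking matrices come from a `sweep.json` sidecar in the
DICOM directory when present (same schema as the manifest, with `matrix`
entries holding 16 row-major numbers); otherwise identity matrices are
emitted. Pixel spacing comes from the DICOM PixelSpacing tag (default 1 mm).
"""
import json
import os
import sys

import numpy as np
import pydicom


def png_write_grey(arr, path):
    # minimal 8-bit greyscale PNG writer (no external imaging dependency)
    import struct
    import zlib

    h, w = arr.shape
    raw = b"".join(b"\x00" + arr[i].astype(np.uint8).tobytes() for i in range(h))

    def chunk(tag, data):
        c = tag + data
        return struct.pack(">I", len(data)) + c + struct.pack(">I", zlib.crc32(c))

    with open(path, "wb") as f:
        f.write(b"\x89PNG\r\n\x1a\n")
        f.write(chunk(b"IHDR", struct.pack(">IIBBBBB", w, h, 8, 0, 0, 0, 0)))
        f.write(chunk(b"IDAT", zlib.compress(raw)))
        f.write(chunk(b"IEND", b""))


def main(src, dst):
    files = [f for f in sorted(os.listdir(src)) if f.lower().endswith((".dcm", ".ima"))]
    if not files:
        files = [f for f in sorted(os.listdir(src))
                 if os.path.isfile(os.path.join(src, f)) and not f.endswith(".json")]
    ds_list = []
    for f in files:
        try:
            ds_list.append((f, pydicom.dcmread(os.path.join(src, f))))
        except Exception:
            continue
    if not ds_list:
        sys.exit("no readable DICOM files in " + src)
    ds_list.sort(key=lambda t: (getattr(t[1], "InstanceNumber", 0), t[0]))

    sidecar = {}
    sc_path = os.path.join(src, "sweep.json")
    if os.path.exists(sc_path):
        with open(sc_path) as fh:
            sidecar = json.load(fh)

    os.makedirs(dst, exist_ok=True)
    frames = []
    spacing = sidecar.get("pixel_spacing_mm")
    for k, (fname, ds) in enumerate(ds_list):
        px = ds.pixel_array.astype(np.float64)
        if px.ndim == 3:
            px = px[..., 0]
        if px.max() > 255:
            px = px / px.max() * 255.0
        img_name, mat_name = "f%04d.png" % k, "f%04d.txt" % k
        png_write_grey(np.round(px), os.path.join(dst, img_name))
        mat = np.eye(4)
        sc_frames = sidecar.get("frames", [])
        if k < len(sc_frames) and "matrix" in sc_frames[k]:
            mat = np.asarray(sc_frames[k]["matrix"], dtype=float).reshape(4, 4)
        with open(os.path.join(dst, mat_name), "w") as fh:
            for row in mat:
                fh.write(" ".join("%.17g" % v for v in row) + "\n")
        if spacing is None and hasattr(ds, "PixelSpacing"):
            spacing = [float(ds.PixelSpacing[0]), float(ds.PixelSpacing[1])]
        frames.append({"image": img_name, "matrix": mat_name})
    manifest = {"id": sidecar.get("id", os.path.basename(src.rstrip("/"))),
                "pixel_spacing_mm": spacing or [1.0, 1.0],
                "frames": frames}
    with open(os.path.join(dst, "sweep.json"), "w") as fh:
        json.dump(manifest, fh)


if __name__ == "__main__":
    if len(sys.argv) != 3:
        sys.exit(__doc__)
    main(sys.argv[1], sys.argv[2])
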