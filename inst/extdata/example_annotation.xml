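<?xml version="1.0"?>
<annotation>
  <folder>images</folder>
  <filename>example.png</filename>
  <size><width>320</width><height>320</height><depth>3</depth></size>
  <object>
    <name>fillingwheat</name>
    <pose>Unspecified</pose>
    <truncated>0</truncated>
    <difficult>0</difficult>
    <bndbox><xmin>41</xmin><ymin>58</ymin><xmax>73</xmax><ymax>121</ymax></bndbox>
  </object>
  <object>
    <name>ripewheat</name>
    <pose>Unspecified</pose>
    <truncated>0</truncated>
    <difficult>0</difficult>
    <bndbox><xmin>140</xmin><ymin>200</ymin><xmax>185</xmax><ymax>260</ymax></bndbox>
  </object>
</annotation>
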