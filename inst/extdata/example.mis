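<?xml version="1.0" encoding="UTF-8"?>
<ImagingDocument dialect="prismms-mis-1">
  <MethodName>prescan_200um</MethodName>
  <Raster>200</Raster>
  <Transform>200 0 0 200 0 0</Transform>
  <Area Name="well_A1">
    <Point>0,0</Point>
    <Point>2000,0</Point>
    <Point>2000,2000</Point>
    <Point>0,2000</Point>
    <Point>0,0</Point>
  </Area>
</ImagingDocument>
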