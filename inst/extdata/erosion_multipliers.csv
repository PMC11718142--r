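land_use,slope,multiplier
cropping,flat,300
cropping,rolling,500
cropping,easy,650
cropping,steep,800
vegetables,flat,400
vegetables,rolling,600
vegetables,easy,750
vegetables,steep,800
dairy,flat,70
dairy,rolling,120
dairy,easy,200
dairy,steep,300
sheep-and-beef,flat,100
sheep-and-beef,rolling,250
sheep-and-beef,easy,500
sheep-and-beef,steep,800
deer,flat,120
deer,rolling,300
deer,easy,550
deer,steep,800
forestry,flat,70
forestry,rolling,90
forestry,easy,120
forestry,steep,200
horticulture,flat,150
horticulture,rolling,250
horticulture,easy,400
horticulture,steep,600
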