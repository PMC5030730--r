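"name","family","order"
"IntegratedIntensity","Intensity",1
"MeanIntensity","Intensity",2
"StdIntensity","Intensity",3
"MinIntensity","Intensity",4
"MaxIntensity","Intensity",5
"IntegratedIntensityEdge","Intensity",6
"MeanIntensityEdge","Intensity",7
"StdIntensityEdge","Intensity",8
"MinIntensityEdge","Intensity",9
"MaxIntensityEdge","Intensity",10
"MassDisplacement","Intensity",11
"LowerQuartileIntensity","Intensity",12
"MedianIntensity","Intensity",13
"MADIntensity","Intensity",14
"UpperQuartileIntensity","Intensity",15
"CenterMassIntensityRow","Intensity",16
"CenterMassIntensityCol","Intensity",17
"Area","Shape",18
"Perimeter","Shape",19
"FormFactor","Shape",20
"Compactness","Shape",21
"Eccentricity","Shape",22
"MajorAxisLength","Shape",23
"MinorAxisLength","Shape",24
"Orientation","Shape",25
"Solidity","Shape",26
"Extent","Shape",27
"EulerNumber","Shape",28
"EquivalentDiameter","Shape",29
"MaxFeretDiameter","Shape",30
"MinFeretDiameter","Shape",31
"MeanRadius","Shape",32
"MedianRadius","Shape",33
"MaximumRadius","Shape",34
"NumberOfNeighbors","Neighbors",35
"PercentTouching","Neighbors",36
"FirstClosestObjectNumber","Neighbors",37
"FirstClosestDistance","Neighbors",38
"SecondClosestObjectNumber","Neighbors",39
"SecondClosestDistance","Neighbors",40
"AngleBetweenNeighbors","Neighbors",41
"FracAtD_1of4","Radial",42
"FracAtD_2of4","Radial",43
"FracAtD_3of4","Radial",44
"FracAtD_4of4","Radial",45
"MeanFrac_1of4","Radial",46
"MeanFrac_2of4","Radial",47
"MeanFrac_3of4","Radial",48
"MeanFrac_4of4","Radial",49
"RadialCV_1of4","Radial",50
"RadialCV_2of4","Radial",51
"RadialCV_3of4","Radial",52
"RadialCV_4of4","Radial",53
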