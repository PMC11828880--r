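method,member,mAP,mAR,mAA,mAF1
teacher,ConvNext,0.76554,0.74104,0.99174,0.75198
teacher,RegnetX,0.75315,0.72520,0.98984,0.73597
teacher,VIT,0.77396,0.75509,0.99244,0.76366
teacher,Swin V2,0.76759,0.75541,0.99294,0.75917
teacher,Ensemble,0.80506,0.78418,0.99174,0.79269
student,ConvNext,0.79554,0.76104,0.99174,0.76198
student,RegnetX,0.77315,0.74520,0.98984,0.74597
student,VIT,0.79396,0.77509,0.99244,0.77366
student,Swin V2,0.79759,0.78541,0.99294,0.76917
student,Ensemble,0.83457,0.82899,0.99174,0.80880
label smoothing,ConvNext,0.79554,0.76104,0.99174,0.76198
label smoothing,RegnetX,0.77315,0.74520,0.98984,0.74597
label smoothing,VIT,0.79396,0.77509,0.99244,0.77366
label smoothing,Swin V2,0.79759,0.78541,0.99294,0.76917
label smoothing,Ensemble,0.78920,0.77857,0.98565,0.78741
weighted data loaders,ConvNext,0.84578,0.83104,0.99568,0.79835
weighted data loaders,RegnetX,0.82290,0.81520,0.99112,0.76922
weighted data loaders,VIT,0.83645,0.82509,0.99823,0.78124
weighted data loaders,Swin V2,0.84595,0.83541,0.99676,0.79978
weighted data loaders,Ensemble,0.86569,0.84457,0.99725,0.85880
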